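# Independent brute-force oracles.  These re-derive the similarity relation
# and the shortest-path cost with plain loops / exhaustive relaxation and
# never call the kernels they check.

# index of the point of B closest to a (ties -> lower index)
oracle_nearest <- function(a, B) {
    d <- sqrt(colSums((t(B) - a)^2))
    which.min(d)
}

# duplicate-excluding closest-point relation, returned as a sorted key set
oracle_point_relation <- function(A, B) {
    keys <- character(0)
    for (i in seq_len(nrow(A)))
        keys <- c(keys, paste(i, oracle_nearest(A[i, ], B)))
    for (j in seq_len(nrow(B)))
        keys <- c(keys, paste(oracle_nearest(B[j, ], A), j))
    sort(unique(keys))
}

oracle_mcd <- function(A, B) {
    keys <- oracle_point_relation(A, B)
    d <- vapply(strsplit(keys, " "), function(k) {
        i <- as.integer(k[1]); j <- as.integer(k[2])
        sqrt(sum((A[i, ] - B[j, ])^2))
    }, numeric(1))
    mean(d)
}

# pairwise trimming per the stated end-correspondence rules
oracle_trim <- function(A, B) {
    nA <- nrow(A); nB <- nrow(B)
    dFwd <- sqrt(sum((A[1, ] - B[1, ])^2)) + sqrt(sum((A[nA, ] - B[nB, ])^2))
    dRev <- sqrt(sum((A[1, ] - B[nB, ])^2)) + sqrt(sum((A[nA, ] - B[1, ])^2))
    if (dRev < dFwd) B <- B[nB:1, , drop = FALSE]
    a0 <- 1; a1 <- nA; b0 <- 1; b1 <- nB
    interior <- function(idx, n) idx != 1 && idx != n
    # start end
    jB <- oracle_nearest(A[1, ], B); jA <- oracle_nearest(B[1, ], A)
    iB <- interior(jB, nB); iA <- interior(jA, nA)
    if (xor(iA, iB)) { if (iB) b0 <- jB else a0 <- jA }
    # far end
    jB <- oracle_nearest(A[nA, ], B); jA <- oracle_nearest(B[nB, ], A)
    iB <- interior(jB, nB); iA <- interior(jA, nA)
    if (xor(iA, iB)) { if (iB) b1 <- jB else a1 <- jA }
    if (a1 - a0 < 1) { a0 <- 1; a1 <- nA }
    if (b1 - b0 < 1) { b0 <- 1; b1 <- nB }
    list(a = A[a0:a1, , drop = FALSE], b = B[b0:b1, , drop = FALSE])
}

oracle_mcd_trimmed <- function(A, B) {
    tr <- oracle_trim(A, B)
    oracle_mcd(tr$a, tr$b)
}

# exhaustive tract similarity over all fiber pairs
oracle_tract_similarity <- function(F, G) {
    D <- matrix(0, length(F), length(G))
    for (i in seq_along(F))
        for (j in seq_along(G))
            D[i, j] <- oracle_mcd_trimmed(F[[i]], G[[j]])
    keys <- character(0)
    for (i in seq_along(F)) keys <- c(keys, paste(i, which.min(D[i, ])))
    for (j in seq_along(G)) keys <- c(keys, paste(which.min(D[, j]), j))
    keys <- sort(unique(keys))
    d <- vapply(strsplit(keys, " "), function(k)
        D[as.integer(k[1]), as.integer(k[2])], numeric(1))
    list(s_avg = mean(d), s_min = min(d), n = length(d))
}

# Exhaustive shortest-path relaxation over the (node, arrival-offset) state
# space of a SearchGrid: Bellman-Ford iterated to a fixed point.  Edge
# costs go through the package's stepCost on interpolated midpoint tensors
# (the shared cost model); the search itself is independent of A*.
oracle_min_cost <- function(grid, field, startNode, goalMask, params) {
    dims <- grid@dims
    off <- grid@offsets
    M <- nrow(off)
    nidx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                                  k = 0:(dims[3] - 1)))
    nn <- nrow(nidx)
    pos <- t(t(nidx * grid@spacing) + grid@origin)
    # enumerate edges (from-node, offset) with finite cost
    from <- rep(seq_len(nn), times = M)
    offi <- rep(seq_len(M), each = nn)
    ti <- nidx[from, 1] + off[offi, 1]
    tj <- nidx[from, 2] + off[offi, 2]
    tk <- nidx[from, 3] + off[offi, 3]
    ok <- ti >= 0 & ti < dims[1] & tj >= 0 & tj < dims[2] & tk >= 0 & tk < dims[3]
    from <- from[ok]; offi <- offi[ok]
    to <- 1 + ti[ok] + dims[1] * (tj[ok] + dims[2] * tk[ok])
    mid <- (pos[from, , drop = FALSE] + pos[to, , drop = FALSE]) / 2
    tmid <- interpolateTensor(field, mid)
    w <- vapply(seq_along(from), function(e)
        stepCost(tmid[e, ], grid@offDirs[offi[e], ], grid@offLen[offi[e]],
                 params), numeric(1))
    keep <- is.finite(w) & attr(tmid, "inside")
    from <- from[keep]; to <- to[keep]; offi <- offi[keep]; w <- w[keep]

    # states: (node, arrival offset); compatible transitions by bending limit
    cosb <- cos(params@bendingAngle * pi / 180)
    compat <- tcrossprod(grid@offDirs) >= cosb - 1e-12
    dist <- matrix(Inf, nn, M)          # dist[n, a]: min cost arriving at n via a
    startLin <- 1 + startNode[1] + dims[1] * (startNode[2] + dims[2] * startNode[3])
    # first move from the start (no bending constraint)
    init <- from == startLin
    for (e in which(init))
        dist[to[e], offi[e]] <- min(dist[to[e], offi[e]], w[e])
    repeat {
        changed <- FALSE
        new <- dist
        for (a in seq_len(M)) {
            # relax all edges whose offset is compatible with arrival a
            has <- is.finite(dist[, a])
            if (!any(has)) next
            sel <- has[from] & compat[a, offi]
            if (!any(sel)) next
            cand <- dist[from[sel], a] + w[sel]
            tsel <- to[sel]; osel <- offi[sel]
            o <- order(cand)
            key <- paste(tsel[o], osel[o])
            first <- !duplicated(key)
            imp <- cbind(tsel[o][first], osel[o][first])
            v <- cand[o][first]
            upd <- v < new[imp]
            if (any(upd)) {
                new[imp[upd, , drop = FALSE]] <- v[upd]
                changed <- TRUE
            }
        }
        if (!changed) break
        dist <- new
    }
    goal <- which(goalMask)
    if (startLin %in% goal) return(0)
    min(dist[goal, ])
}
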