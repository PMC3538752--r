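test_that("neighbor offset sets have the documented structure", {
    off <- neighborOffsets("74")
    expect_equal(nrow(off), 74L)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_setequal(key(off), key(-off))               # central symmetry
    expect_false(any(rowSums(abs(off)) == 0))
    # no offset is a multiple of a shorter one
    expect_false(any(apply(off, 1, function(o) all(o / 2 == round(o / 2)))))
    off98 <- neighborOffsets("98")
    expect_equal(nrow(off98), 98L)
    extra <- setdiff(key(off98), key(off))
    expect_length(extra, 24L)                          # the (2,2,1) class
})

test_that("grid spacing realizes the configured average step", {
    f <- homogeneous_field(dims = c(20, 20, 20))
    g <- buildGrid(f, params = gsParams(avgStep = 2))
    expect_equal(mean(g@offLen), 2, tolerance = 0.02)
    expect_lt(min(g@offLen), 2)                        # min < mean < max
    expect_gt(max(g@offLen), 2)
    g15 <- buildGrid(f, params = gsParams(avgStep = 1.5))
    expect_equal(mean(g15@offLen), 1.5, tolerance = 0.02)
    # bbox restricts the lattice
    bb <- rbind(c(0, 0, 0), c(12, 12, 12))
    gb <- buildGrid(f, bbox = bb, params = gsParams())
    nodes <- gstract:::.node_world(gb, as.matrix(expand.grid(
        i = 0:(gb@dims[1] - 1), j = 0:(gb@dims[2] - 1), k = 0:(gb@dims[3] - 1))))
    expect_true(all(nodes >= -1e-9 & nodes <= 12 + 1e-9))
    expect_error(buildGrid(f, bbox = rbind(c(100, 100, 100), c(120, 120, 120))),
                 "intersect")
})

test_that("propagation probability has no isotropic bias and peaks along e1", {
    iso <- c(1, 1, 1, 0, 0, 0) * 1e-3
    for (v in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3)))
        expect_equal(propagationProbability(iso, v), 0)
    t6 <- c(2, 1, 1, 0, 0, 0) * 1e-3
    expect_equal(propagationProbability(t6, c(1, 0, 0)), 0.5)
    expect_equal(propagationProbability(t6, c(0, 0, 1)), 0)   # v = e3
    set.seed(8)
    for (r in 1:20) {      # v'Dv = lambda3 along e3 for any tensor
        t6 <- random_spd_tensor()
        e <- tensorEigen(t6)
        expect_equal(propagationProbability(t6, e$vectors[, 3]), 0,
                     tolerance = 1e-9)
        expect_gte(propagationProbability(t6, e$vectors[, 1]), 0)
    }
})

test_that("divergence factor follows the shape-dependent cosine rules", {
    e <- tensorEigen(c(1.7e-3, 3e-4, 3e-4, 0, 0, 0))
    s <- westinShape(e$values)
    expect_equal(s$shapeClass, "linear")
    expect_equal(divergenceFactor(e, s, c(1, 0, 0)), 1)
    expect_equal(divergenceFactor(e, s, c(0, 1, 0)), 0, tolerance = 1e-9)
    ep <- tensorEigen(c(1e-3, 1e-3, 1e-4, 0, 0, 0))
    sp <- westinShape(ep$values)
    expect_equal(sp$shapeClass, "planar")
    v <- (ep$vectors[, 1] + ep$vectors[, 3]) / sqrt(2)
    expect_equal(divergenceFactor(ep, sp, v), sqrt(0.5), tolerance = 1e-9)
})

test_that("step cost is clipped, monotone and infinite on forbidden edges", {
    p <- gsParams(faThreshold = 0)
    iso <- c(1, 1, 1, 0, 0, 0) * 1e-3
    expect_equal(stepCost(iso, c(1, 0, 0), 2, p), 2)          # p-hat = 0
    lin <- c(1e-3, 0, 0, 0, 0, 0)                             # FA = p = d = 1
    expect_equal(stepCost(lin, c(1, 0, 0), 2, p), 2 * 1e-3)   # epsilon floor
    t6 <- c(2, 1, 1, 0, 0, 0) * 1e-3
    ref <- 2 * (1 - 0.5 * 1 * fractionalAnisotropy(c(2, 1, 1)))
    expect_equal(stepCost(t6, c(1, 0, 0), 2, p), ref, tolerance = 1e-12)
    # alignment can only lower the cost
    expect_lte(stepCost(t6, c(1, 0, 0), 2, p), stepCost(t6, c(0, 1, 0), 2, p))
    # below the FA threshold the edge is forbidden
    expect_equal(stepCost(iso, c(1, 0, 0), 2, gsParams(faThreshold = 0.2)), Inf)
    for (v in list(c(1, 0, 0), c(0, 1, 1) / sqrt(2)))
        expect_true(stepCost(random_spd_tensor(), v, 2, p) >= 2e-3)
})

test_that("A* matches the exhaustive-relaxation oracle on random fields", {
    set.seed(21)
    for (trial in 1:3) {
        dims <- sample(4:5, 3, replace = TRUE)
        tens <- array(0, c(dims, 6))
        tm <- t(vapply(seq_len(prod(dims)), function(i) random_spd_tensor(),
                       numeric(6)))
        tens[] <- tm
        fld <- tensorField(tens, voxelSize = 2)
        params <- gsParams(faThreshold = 0.1,
                           bendingAngle = sample(c(60, 90), 1))
        grid <- buildGrid(fld, params = params)
        roiA <- array(FALSE, dims); roiA[1, 1, 1] <- TRUE
        roiB <- array(FALSE, dims)
        roiB[dims[1], dims[2], dims[3]] <- TRUE
        start <- gstract:::.grid_nodes_in_mask(grid, roiA, fld@affine)[1, ]
        r <- astarSearch(grid, fld, roiA, roiB, params, start = start)
        goal <- gstract:::.grid_goal(grid, roiB, fld@affine)
        ref <- oracle_min_cost(grid, fld, start, goal, params)
        if (is(r, "Fiber")) {
            expect_equal(provenance(r)$cost, ref, tolerance = 1e-9)
        } else {
            expect_true(is.infinite(ref))
        }
    }
})

test_that("A* respects the bending limit and finds the straight connection", {
    f <- homogeneous_field(dims = c(25, 7, 7))
    dims <- dim(f)
    roiA <- array(FALSE, dims); roiA[1, 4, 4] <- TRUE
    roiB <- array(FALSE, dims); roiB[25, 4, 4] <- TRUE
    params <- gsParams(faThreshold = 0.3)
    grid <- buildGrid(f, params = params)
    r <- astarSearch(grid, f, roiA, roiB, params)
    expect_s4_class(r, "Fiber")
    p <- fiberPoints(r)
    # within one grid spacing of the straight line
    expect_lt(max(abs(p[, 2] - 6)), grid@spacing + 1e-9)
    expect_lt(max(abs(p[, 3] - 6)), grid@spacing + 1e-9)
    # bending constraint at every interior node
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    dots <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
    expect_gte(min(dots), cos(params@bendingAngle * pi / 180) - 1e-9)
    # start inside roi_b: degenerate zero-cost result
    r0 <- astarSearch(grid, f, roiB, roiB, params)
    expect_true(isTRUE(r0$degenerate) || is(r0, "Fiber"))
})

test_that("pathway reconstruction equals per-start A* and honors ROIs", {
    pd <- buildPhantom(tiny_straight())
    fld <- phantomField(pd)
    params <- gsParams(faThreshold = 0.6, faFallback = 0.6)
    tr <- reconstructPathway(fld, pd@roiA, pd@roiB, params = params)
    expect_gt(length(tr), 0)
    aff <- fld@affine
    for (f in fibers(tr)) {
        p <- fiberPoints(f)
        expect_true(gstract:::.points_in_mask(p[1, , drop = FALSE],
                                              pd@roiA, aff))
        expect_true(gstract:::.points_in_mask(p[nrow(p), , drop = FALSE],
                                              pd@roiB, aff))
    }
    # the shared sweep returns the same minimum cost as per-start A*
    grid <- buildGrid(fld, NULL, params)
    for (i in c(1L, length(tr))) {
        f <- tr[[i]]
        r <- astarSearch(grid, fld, pd@roiA, pd@roiB, params,
                         start = provenance(f)$start)
        expect_equal(provenance(r)$cost, provenance(f)$cost, tolerance = 1e-9)
    }
    # failure at both thresholds is explicit
    iso <- isotropic_field(dims = c(10, 10, 10))
    roiA <- array(FALSE, c(10, 10, 10)); roiA[2, 5, 5] <- TRUE
    roiB <- array(FALSE, c(10, 10, 10)); roiB[9, 5, 5] <- TRUE
    bad <- reconstructPathway(iso, roiA, roiB, params = gsParams())
    expect_length(bad, 0)
    expect_true(provenance(bad)$failed)
})

test_that("the FA fallback rescues a search blocked at the strict threshold", {
    # tube whose FA sits between the fallback and strict thresholds
    f <- homogeneous_field(dims = c(16, 7, 7),
                           lambda = c(1.05e-3, 7e-4, 7e-4))  # FA ~ 0.24
    dims <- dim(f)
    roiA <- array(FALSE, dims); roiA[1, 4, 4] <- TRUE
    roiB <- array(FALSE, dims); roiB[16, 4, 4] <- TRUE
    tr <- reconstructPathway(f, roiA, roiB,
                             params = gsParams(faThreshold = 0.3,
                                               faFallback = 0.15))
    expect_gt(length(tr), 0)
    expect_equal(provenance(tr)$faThreshold, 0.15)
})

test_that("bounding boxes confine every reconstructed path", {
    f <- homogeneous_field(dims = c(25, 9, 9))
    dims <- dim(f)
    roiA <- array(FALSE, dims); roiA[2, 5, 5] <- TRUE
    roiB <- array(FALSE, dims); roiB[24, 5, 5] <- TRUE
    bb <- rbind(c(0, 4, 4), c(48, 12, 12))
    tr <- reconstructPathway(f, roiA, roiB, bbox = bb, params = gsParams(0.3))
    expect_gt(length(tr), 0)
    for (fb in fibers(tr)) {
        p <- fiberPoints(fb)
        expect_true(all(t(p) >= bb[1, ] - 1e-9 & t(p) <= bb[2, ] + 1e-9))
    }
})
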