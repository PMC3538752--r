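#' @include methods.R phantom.R tracking.R global-search.R similarity.R fiber-io.R
NULL

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples.  For a
#' combined sample size of at most 12 the two-sided p-value is computed by
#' exact enumeration of all group assignments (valid under ties); larger
#' samples use the normal approximation with tie correction and
#' continuity correction.  `U` is the statistic of `a` (number of pairs
#' with the `a` value smaller, ties counting one half).
#'
#' @param a,b numeric samples, both non-empty.
#' @param alpha significance level reported alongside (default 0.05).
#' @return list with `U`, `p`, `significant`, `method`, and `allTied`
#'   (p = 1 with a flag when every value is identical).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))$p     # exact: 1/3
#' @export
mannWhitneyU <- function(a, b, alpha = 0.05) {
    stopifnot(length(a) > 0, length(b) > 0)
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    uStat <- function(idx) {
        r <- rank(pooled)
        sum(r[idx]) - n1 * (n1 + 1) / 2
    }
    U <- uStat(seq_len(n1))
    if (length(unique(pooled)) == 1L)
        return(list(U = U, p = 1, significant = FALSE, method = "degenerate",
                    allTied = TRUE))
    n <- n1 + n2
    if (n <= 12L) {
        r <- rank(pooled)
        combos <- utils::combn(n, n1)
        us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
        dev <- abs(us - n1 * n2 / 2)
        p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-9)
        method <- "exact enumeration"
    } else {
        r <- rank(pooled)
        ties <- table(r)
        sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        dev <- U - n1 * n2 / 2
        z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)   # continuity correction
        p <- min(1, 2 * min(stats::pnorm(z), 1 - stats::pnorm(z)))
        method <- "normal approximation"
    }
    list(U = U, p = p, significant = p < alpha, method = method,
         allTied = FALSE)
}

#' Configure a phantom benchmark run
#'
#' @param phantoms phantom kinds to run.
#' @param snrs SNR levels (the protocol of interest uses 15 and 30).
#' @param methods any of `"sp"`, `"td"`, `"gs"`.
#' @param seed global seed; every noise realization derives from it.
#' @param faOffset per-phantom FA thresholds are set this far below the
#'   average FA in the main part of the pathway, for all methods.
#' @param stepLength tracker step, mm.
#' @param gs a [GSParams-class] carrying grid and bending settings (the
#'   FA threshold is overridden per phantom).
#' @param outputDir optional directory for volumes/streamlines/reports.
#' @return list of class `"gstract_config"`.
#' @export
suiteConfig <- function(phantoms = c("branching", "kissing", "spiral"),
                        snrs = c(15, 30), methods = c("sp", "td", "gs"),
                        seed = 1, faOffset = 0.1, stepLength = 0.5,
                        gs = gsParams(), outputDir = NULL) {
    stopifnot(all(methods %in% c("sp", "td", "gs")))
    structure(list(phantoms = phantoms, snrs = snrs, methods = methods,
                   seed = seed, faOffset = faOffset, stepLength = stepLength,
                   gs = gs, outputDir = outputDir),
              class = "gstract_config")
}

# per-phantom FA threshold: mean fitted FA in the pathway core, minus offset
.phantom_threshold <- function(field, pd, offset) {
    centers <- .voxel_centers(dim(field), field@affine)
    core <- rep(FALSE, nrow(centers))
    # "main part": voxels near the centerline; never narrower than a voxel
    rCore <- max(pd@bundle@radius / 2, 0.75 * max(field@voxelSize))
    for (cv in pd@bundle@curves) {
        d <- cpp_polyline_distance(centers, cv$points)$distance
        core <- core | d <= rCore
    }
    mean(faMap(field)[core]) - offset
}

# fraction of the ground-truth first spiral cycle lying within one tube
# radius of the longest fiber that reaches the outer ROI
.spiral_coverage <- function(pd, tract) {
    cv <- pd@bundle@curves[[1L]]
    al <- c(0, cumsum(sqrt(rowSums(diff(cv$points)^2))))
    turns <- pd@spec@spiralTurns
    firstCycle <- cv$points[al <= al[length(al)] / turns, , drop = FALSE]
    aff <- pd@trueField@affine
    cand <- Filter(function(f) .fiber_hits_mask(f@points, pd@roiA, aff),
                   tract@fibers)
    if (length(cand) == 0L) return(0)
    lens <- vapply(cand, function(f) {
        a <- arcLength(f)
        a[length(a)]
    }, numeric(1))
    longest <- cand[[which.max(lens)]]
    d <- cpp_polyline_distance(firstCycle, longest@points)$distance
    mean(d <= pd@bundle@radius)
}

# azimuthal angle (deg) swept around a planar center by a fiber polyline:
# range of the unwrapped polar angle, insensitive to step-level jitter
.azimuthal_sweep <- function(points, center) {
    th <- atan2(points[, 2] - center[2], points[, 1] - center[1])
    d <- diff(th)
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    un <- cumsum(c(th[1], d))
    (max(un) - min(un)) * 180 / pi
}

# total turning angle (deg) along a fiber polyline
.total_turning <- function(points) {
    if (nrow(points) < 3L) return(0)
    seg <- diff(points)
    seg <- seg / sqrt(rowSums(seg^2))
    dots <- pmin(1, pmax(-1, rowSums(seg[-1L, , drop = FALSE] *
                                     seg[-nrow(seg), , drop = FALSE])))
    sum(acos(dots)) * 180 / pi
}

#' Run the phantom benchmark suite
#'
#' For every (phantom, SNR) cell: generate the phantom with a seed derived
#' from the configured one, fit tensors from the noisy DWI, derive the
#' per-phantom FA threshold, run each configured method, record connection
#' success, pairwise tract similarity for every connected method pair, and
#' (for the spiral) the first-cycle coverage of the deterministic
#' trackers.  Failures are recorded per cell and never abort the suite.
#' Runs with the same configuration are identical.
#'
#' @param config a [suiteConfig()] list.
#' @return list of class `"gstract_report"`: per-cell results plus the
#'   configuration echo.
#' @export
runPhantomSuite <- function(config = suiteConfig()) {
    cells <- list()
    cellSeed <- config$seed
    for (kind in config$phantoms) {
        for (snr in config$snrs) {
            cellSeed <- cellSeed + 1L
            t0 <- proc.time()[["elapsed"]]
            cell <- list(phantom = kind, snr = snr, seed = cellSeed)
            pd <- buildPhantom(phantomSpec(kind, snr = snr, seed = cellSeed))
            field <- phantomField(pd)
            thr <- .phantom_threshold(field, pd, config$faOffset)
            cell$faThreshold <- thr
            tracts <- list()
            connected <- logical(0)
            for (m in config$methods) {
                tr <- tryCatch({
                    if (m == "gs") {
                        p <- config$gs
                        p@faThreshold <- thr
                        p@faFallback <- thr     # per-phantom threshold, no fallback
                        reconstructPathway(field, pd@roiA, pd@roiB, params = p)
                    } else {
                        runTracker(field, pd@roiA, pd@roiB,
                                   trackingParams(stepLength = config$stepLength,
                                                  faThreshold = thr),
                                   method = m)
                    }
                }, error = function(e) {
                    fiberTract(provenance = list(method = m,
                                                 error = conditionMessage(e)))
                })
                tracts[[m]] <- tr
                connected[m] <- length(tr) > 0L
            }
            cell$connected <- connected
            # pairwise similarity among connected methods
            sims <- list()
            ms <- config$methods
            if (length(ms) >= 2L) {
                for (i in seq_len(length(ms) - 1L)) {
                    for (j in (i + 1L):length(ms)) {
                        if (!connected[ms[i]] || !connected[ms[j]]) next
                        key <- paste(ms[i], ms[j], sep = "-")
                        sims[[key]] <- tractSimilarity(tracts[[ms[i]]],
                                                       tracts[[ms[j]]],
                                                       step = config$stepLength,
                                                       field = field)
                    }
                }
            }
            cell$similarity <- sims
            if (kind == "spiral") {
                # coverage is measured on all fibers reaching the outer ROI,
                # whether or not they connect to the inner one
                cov <- list()
                for (m in intersect(c("sp", "td"), ms)) {
                    allA <- runTracker(field, pd@roiA, pd@roiA,
                                       trackingParams(stepLength = config$stepLength,
                                                      faThreshold = thr),
                                       method = m)
                    cov[[m]] <- .spiral_coverage(pd, allA)
                }
                cell$spiralCoverage <- cov
                if ("gs" %in% ms && connected["gs"]) {
                    ctr <- .volume_center(pd@spec)
                    sweep <- vapply(tracts[["gs"]]@fibers,
                                    function(f) .azimuthal_sweep(f@points, ctr),
                                    numeric(1))
                    cell$gsMaxSweep <- max(sweep)
                }
            }
            cell$runtime <- proc.time()[["elapsed"]] - t0
            if (!is.null(config$outputDir)) {
                dir.create(config$outputDir, showWarnings = FALSE,
                           recursive = TRUE)
                for (m in names(tracts))
                    writeFibers(tracts[[m]],
                                file.path(config$outputDir,
                                          sprintf("%s_snr%g_%s.trk", kind, snr, m)),
                                affine = field@affine,
                                voxelSize = field@voxelSize, dims = dim(field))
            }
            cells[[sprintf("%s_snr%g", kind, snr)]] <- cell
        }
    }
    structure(list(cells = cells, config = config), class = "gstract_report")
}

#' @export
print.gstract_report <- function(x, ...) {
    cat("Phantom benchmark report\n")
    for (nm in names(x$cells)) {
        cell <- x$cells[[nm]]
        conn <- paste(sprintf("%s:%s", names(cell$connected),
                              ifelse(cell$connected, "connected", "failed")),
                      collapse = "  ")
        cat(sprintf("  %-16s FA thr %.3f  %s\n", nm, cell$faThreshold, conn))
        for (key in names(cell$similarity)) {
            s <- cell$similarity[[key]]
            cat(sprintf("      %-8s S_avg %6.2f mm  S_min %6.2f mm  (N=%d)\n",
                        key, s@sAvg, s@sMin, s@nPairs))
        }
        if (!is.null(cell$spiralCoverage))
            for (m in names(cell$spiralCoverage))
                cat(sprintf("      %s first-cycle coverage %.2f\n", m,
                            cell$spiralCoverage[[m]]))
    }
    invisible(x)
}

#' Flatten a benchmark report to a data frame
#'
#' One row per (phantom, SNR, method) with connection status, plus
#' similarity rows per compared pair.
#'
#' @param report a `gstract_report`.
#' @return list of data frames `connections` and `similarities`.
#' @export
reportTables <- function(report) {
    conn <- do.call(rbind, lapply(report$cells, function(cell)
        data.frame(phantom = cell$phantom, snr = cell$snr,
                   method = names(cell$connected),
                   connected = unname(cell$connected),
                   faThreshold = cell$faThreshold)))
    sims <- do.call(rbind, lapply(report$cells, function(cell) {
        if (length(cell$similarity) == 0L) return(NULL)
        do.call(rbind, lapply(names(cell$similarity), function(key)
            data.frame(phantom = cell$phantom, snr = cell$snr, pair = key,
                       sAvg = cell$similarity[[key]]@sAvg,
                       sMin = cell$similarity[[key]]@sMin,
                       nPairs = cell$similarity[[key]]@nPairs)))
    }))
    rownames(conn) <- NULL
    if (!is.null(sims)) rownames(sims) <- NULL
    list(connections = conn, similarities = sims)
}
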