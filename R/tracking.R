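#' @include methods.R utils.R tensor-field.R
NULL

#' Seed points for deterministic tracking
#'
#' One seed at the center of every voxel whose FA meets the threshold
#' (tracking is initialized in anisotropic white matter, not in functional
#' areas of unclear diffusion direction).  A seed density d > 1 places a
#' regular d^3 sub-grid in each qualifying voxel.
#'
#' @param field a [TensorField-class].
#' @param params a [TrackingParams-class].
#' @return matrix of world-mm seed coordinates (possibly 0 rows).
#' @export
seedPoints <- function(field, params = trackingParams()) {
    fa <- faMap(field)
    idx <- which(fa >= params@faThreshold, arr.ind = TRUE) - 1L
    if (nrow(idx) == 0L) {
        message("no voxels reach the seeding FA threshold")
        return(matrix(numeric(0), 0L, 3L))
    }
    d <- max(1L, round(params@seedDensity))
    if (d > 1L) {
        u <- (seq_len(d) - (d + 1) / 2) / d
        offs <- as.matrix(expand.grid(x = u, y = u, z = u))
        n <- nrow(idx)
        m <- nrow(offs)
        idx <- idx[rep(seq_len(n), each = m), , drop = FALSE] +
            offs[rep(seq_len(m), times = n), , drop = FALSE]
    }
    .voxel2world(field@affine, idx)
}

.method_code <- function(method) {
    method <- match.arg(method, c("sp", "td"))
    c(sp = 0L, td = 1L)[[method]]
}

#' Track a single fiber from a seed
#'
#' Bidirectional propagation at fixed step length: streamline propagation
#' (`"sp"`, 4th-order Runge-Kutta integration of the major-eigenvector
#' field) or tensor deflection (`"td"`, `v_out = normalize(D v_in)` with
#' the tensor normalized by its largest eigenvalue).  Both halves start at
#' the seed along +-e1 and are joined there; propagation stops when FA
#' drops below the threshold, on leaving the volume, or at `maxSteps`.
#'
#' @param field a [TensorField-class].
#' @param seed world-mm coordinate with FA at or above the threshold.
#' @param params a [TrackingParams-class].
#' @param method `"sp"` or `"td"`.
#' @return a [Fiber-class], or `NULL` when the seed is below threshold /
#'   the fiber degenerates to fewer than 2 points.
#' @export
trackFiber <- function(field, seed, params = trackingParams(),
                       method = c("sp", "td")) {
    method <- match.arg(method)
    r <- cpp_track(field@tensors, dim(field), solve(field@affine),
                   matrix(seed, 1L), params@stepLength, params@faThreshold,
                   as.integer(params@maxSteps), .method_code(method))[[1L]]
    if (nrow(r) < 2L) return(NULL)
    fiber(r, provenance = list(method = method, seed = seed,
                               stepLength = params@stepLength,
                               faThreshold = params@faThreshold))
}

#' Whole-volume deterministic tracking between two ROIs
#'
#' Seeds the whole volume, tracks every seed, and keeps the fibers that
#' intersect both ROI masks.  Kept fibers are not clipped to the ROIs.
#'
#' @param field a [TensorField-class].
#' @param roiA,roiB logical voxel masks.
#' @param params a [TrackingParams-class].
#' @param method `"sp"` or `"td"`.
#' @return a [FiberTract-class] (possibly empty) with provenance recording
#'   method, threshold and seed count.
#' @export
runTracker <- function(field, roiA, roiB, params = trackingParams(),
                       method = c("sp", "td")) {
    method <- match.arg(method)
    if (!any(roiA) || !any(roiB)) stop("both ROIs must be non-empty")
    seeds <- seedPoints(field, params)
    prov <- list(method = method, faThreshold = params@faThreshold,
                 stepLength = params@stepLength, nSeeds = nrow(seeds),
                 padding = 0L)
    if (nrow(seeds) == 0L)
        return(fiberTract(provenance = prov))
    raw <- cpp_track(field@tensors, dim(field), solve(field@affine), seeds,
                     params@stepLength, params@faThreshold,
                     as.integer(params@maxSteps), .method_code(method))
    keep <- vapply(raw, function(p) {
        nrow(p) >= 2L &&
            .fiber_hits_mask(p, roiA, field@affine) &&
            .fiber_hits_mask(p, roiB, field@affine)
    }, logical(1))
    fiberTract(lapply(which(keep), function(i)
        fiber(raw[[i]], provenance = list(method = method, seed = seeds[i, ]))),
        provenance = prov)
}

#' Pad an ROI mask
#'
#' Morphological dilation with a box structuring element, one voxel per
#' increment in each dimension; at most 4 voxels total (the adaptive
#' protocol never expands further).
#'
#' @param roi logical voxel mask.
#' @param voxels dilation count, 0..4.
#' @return the dilated mask; the total padding applied is recorded in the
#'   `"padding"` attribute.
#' @export
padROI <- function(roi, voxels) {
    prev <- attr(roi, "padding")
    total <- (if (is.null(prev)) 0L else prev) + voxels
    if (voxels < 0 || total > 4L)
        stop("ROI padding is limited to 4 voxels")
    d <- dim(roi)
    out <- array(FALSE, d)
    if (voxels == 0) {
        out <- roi | out
    } else {
        coords <- which(roi, arr.ind = TRUE)
        u <- -voxels:voxels
        offs <- as.matrix(expand.grid(i = u, j = u, k = u))
        n <- nrow(coords)
        m <- nrow(offs)
        cand <- coords[rep(seq_len(n), each = m), , drop = FALSE] +
            offs[rep(seq_len(m), times = n), , drop = FALSE]
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
        out[cand[ok, , drop = FALSE]] <- TRUE
    }
    attr(out, "padding") <- total
    out
}

#' Adaptive reconstruction with FA relaxation and ROI padding
#'
#' Deterministic trackers may fail to connect low-FA regions.  The
#' protocol: for each FA threshold (0.25, then 0.2) the ROIs are
#' incrementally padded by 0..4 voxels until a non-empty connecting tract
#' is found.  The 0.25 tract is selected iff it required no more than two
#' additional paddings compared to the 0.2 tract; otherwise the 0.2 tract
#' is used.
#'
#' @param field a [TensorField-class].
#' @param roiA,roiB logical voxel masks.
#' @param method `"sp"` or `"td"`.
#' @param params base [TrackingParams-class] (its faThreshold is
#'   overridden by the protocol's thresholds).
#' @param thresholds the two FA thresholds tried, strict then relaxed.
#' @param maxPad maximum ROI padding per threshold.
#' @param tracker tracking backend, `function(field, roiA, roiB, params,
#'   method)`; defaults to [runTracker()].  Exposed so the decision rule
#'   can be exercised on constructed connectivity tables.
#' @return list with `tract` (a [FiberTract-class] or `NULL` on failure)
#'   and `record` (paddings per threshold and the chosen branch).
#' @export
adaptiveReconstruct <- function(field, roiA, roiB, method = c("sp", "td"),
                                params = trackingParams(),
                                thresholds = c(0.25, 0.2), maxPad = 4L,
                                tracker = runTracker) {
    method <- match.arg(method)
    try_threshold <- function(thr) {
        p <- params
        p@faThreshold <- thr
        for (pad in 0:maxPad) {
            tr <- tracker(field, padROI(roiA, pad), padROI(roiB, pad), p, method)
            if (length(tr) > 0L)
                return(list(tract = tr, pad = pad))
        }
        list(tract = NULL, pad = NA_integer_)
    }
    strict <- try_threshold(thresholds[1])
    relaxed <- try_threshold(thresholds[2])
    record <- list(thresholds = thresholds,
                   padStrict = strict$pad, padRelaxed = relaxed$pad)
    if (is.na(strict$pad) && is.na(relaxed$pad)) {
        record$chosen <- "none"
        return(list(tract = NULL, record = record))
    }
    useStrict <- !is.na(strict$pad) &&
        (is.na(relaxed$pad) || strict$pad - relaxed$pad <= 2L)
    record$chosen <- if (useStrict) "strict" else "relaxed"
    chosen <- if (useStrict) strict else relaxed
    tract <- chosen$tract
    tract@provenance$padding <- chosen$pad
    tract@provenance$adaptive <- record
    list(tract = tract, record = record)
}
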