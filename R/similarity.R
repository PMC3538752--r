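#' @include methods.R utils.R tensor-field.R
NULL

.points_of <- function(x) {
    if (is(x, "Fiber")) x@points else {
        m <- as.matrix(x)
        storage.mode(m) <- "double"
        m
    }
}

#' Resample a fiber at equal arc-length spacing
#'
#' Replaces the points by points of equal distance along the polyline
#' (default: the constant 0.5 mm step of the deterministic trackers).
#' First and last input points are preserved and no spatial smoothing is
#' applied: every output point lies on the input polyline.  Grid-bound
#' fibers (variable step length) are normalized this way before any
#' similarity metric.
#'
#' @param f a [Fiber-class] or point matrix.
#' @param step target spacing, mm.
#' @return object of the input kind with resampled points.
#' @export
resampleFiber <- function(f, step = 0.5) {
    p <- .points_of(f)
    if (nrow(p) < 2L) stop("cannot resample a degenerate fiber")
    out <- .resample_polyline(p, step)
    if (is(f, "Fiber")) fiber(out, provenance = f@provenance) else out
}

#' Duplicate-excluding closest-point relation of two fibers
#'
#' Assigns to each point of `fi` the closest point of `fj` and vice versa;
#' the union is kept with duplicate pairs counted once.  Ties break toward
#' the lower index.
#'
#' @param fi,fj fibers or point matrices.
#' @return list with `pairs` (index matrix into `fi`/`fj`) and `distance`.
#' @export
closestPointPairs <- function(fi, fj) {
    cpp_closest_pairs(.points_of(fi), .points_of(fj))
}

#' Mean of closest-point distances between two fibers
#'
#' Arithmetic mean of the Euclidean distances over the deduplicated
#' closest-point relation; symmetric by construction, and outliers are
#' emphasized compared to averaging all bidirectional pairs.
#'
#' @param fi,fj fibers or point matrices.
#' @return distance in mm.
#' @examples
#' a <- cbind(0:10 * 1.0, 0, 0)
#' b <- cbind(0:10 * 1.0, 1, 0)
#' meanClosestDistance(a, b)   # 1
#' @export
meanClosestDistance <- function(fi, fj) {
    cpp_mean_closest_distance(.points_of(fi), .points_of(fj))
}

#' Trim a fiber pair to its corresponding segments
#'
#' Fibers from different methods overlap differently around the ROIs
#' (grid-search fibers terminate in the ROIs, tracker fibers do not).
#' After orienting `fj` to match `fi` (minimal summed endpoint distance),
#' the closest point on the other fiber to each endpoint is examined at
#' both ends: if exactly one of the two closest points is an interior
#' point, the protruding segment beyond it is removed from the fiber that
#' carries it.  Diverging ends (both interior) are never trimmed, so at
#' most one fiber is trimmed at each end.  Trims that would leave fewer
#' than 2 points are refused and recorded.
#'
#' @param fi,fj resampled fibers or point matrices.
#' @return list with trimmed point matrices `a`, `b`, the kept index
#'   ranges `aKeep`, `bKeep`, `reversed` (was `fj` reversed), `refused`
#'   (per fiber) and the removed arc length per fiber, mm.
#' @export
trimPair <- function(fi, fj) {
    A <- .points_of(fi)
    B <- .points_of(fj)
    r <- cpp_trim_pair(A, B)
    alen <- function(p) if (nrow(p) < 2L) 0 else
        sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
    list(a = r$a, b = r$b, aKeep = r$a_keep, bKeep = r$b_keep,
         reversed = r$reversed, refused = r$refused,
         removed = c(alen(A) - alen(r$a), alen(B) - alen(r$b)))
}

.tract_fibers <- function(x, step, resample) {
    fl <- if (is(x, "FiberTract")) lapply(x@fibers, fiberPoints)
          else lapply(x, .points_of)
    if (resample == "none") return(fl)
    lapply(fl, function(p) {
        if (resample == "all") return(.resample_polyline(p, step))
        seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
        uniform <- max(seg) - min(seg) < 1e-6 && abs(seg[1] - step) < 1e-6
        if (uniform) p else .resample_polyline(p, step)
    })
}

#' Geometric similarity of two fiber tracts
#'
#' Builds the duplicate-excluding relation pairing each fiber of `f` with
#' its closest fiber of `g` (trimmed mean closest-point distance) and vice
#' versa, then reports the average (`s_avg`) and minimum (`s_min`)
#' pair distance.  Because duplicate fiber pairs are excluded, outliers
#' weigh more than they would over all pairs.  Fibers are normalized to
#' equal point spacing first: by default only fibers that are not already
#' uniformly sampled at `step` (e.g. grid-bound search fibers) are
#' resampled, mirroring how tracker output is left untouched.
#'
#' @param f,g [FiberTract-class] objects (or lists of fibers / matrices).
#' @param step resampling spacing, mm (the trackers' step length).
#' @param resample `"auto"` (default), `"all"` or `"none"`.
#' @param field optional [TensorField-class]; when given, per-tract
#'   average FA over the trimmed, correlated fibers is included.
#' @return a [SimilarityReport-class].
#' @examples
#' f <- list(cbind(seq(0, 10, 0.5), 0, 0))
#' g <- list(cbind(seq(0, 10, 0.5), 1, 0))
#' sAvg(tractSimilarity(f, g))   # 1
#' @export
tractSimilarity <- function(f, g, step = 0.5, resample = c("auto", "all", "none"),
                            field = NULL) {
    resample <- match.arg(resample)
    F <- .tract_fibers(f, step, resample)
    G <- .tract_fibers(g, step, resample)
    if (length(F) == 0L || length(G) == 0L)
        stop("both tracts must be non-empty")
    r <- cpp_tract_similarity(F, G)
    pairs <- data.frame(i = r$pairs[, 1], j = r$pairs[, 2],
                        distance = r$distance)
    faF <- faG <- NA_real_
    nOut <- 0L
    if (!is.null(field)) {
        fa <- .fa_over_relation(F, G, pairs, field)
        faF <- fa$faF; faG <- fa$faG; nOut <- fa$nOutside
    }
    new("SimilarityReport", sAvg = r$s_avg, sMin = r$s_min,
        nPairs = nrow(pairs), faF = faF, faG = faG, pairs = pairs,
        nOutside = nOut)
}

# mean interpolated FA per tract over the trimmed fibers of the relation
.fa_over_relation <- function(F, G, pairs, field) {
    sampF <- list(); sampG <- list()
    for (r in seq_len(nrow(pairs))) {
        tp <- cpp_trim_pair(F[[pairs$i[r]]], G[[pairs$j[r]]])
        sampF[[r]] <- tp$a
        sampG[[r]] <- tp$b
    }
    fa_of <- function(samples) {
        pts <- do.call(rbind, samples)
        fa <- interpolateFA(field, pts)
        list(mean = mean(fa, na.rm = TRUE), outside = sum(is.na(fa)))
    }
    fF <- fa_of(sampF)
    fG <- fa_of(sampG)
    list(faF = fF$mean, faG = fG$mean,
         nOutside = as.integer(fF$outside + fG$outside))
}

#' Diffusion (FA) similarity of two fiber tracts
#'
#' For each tract the average FA is computed by trilinear interpolation at
#' every point of every trimmed fiber participating in the closest-fiber
#' relation.  Points outside the field are excluded and counted.
#'
#' @param f,g [FiberTract-class] objects (or lists of fibers / matrices).
#' @param field a [TensorField-class].
#' @param step,resample normalization settings as in [tractSimilarity()].
#' @return list with `faF`, `faG` and `nOutside`.
#' @export
faSimilarity <- function(f, g, field, step = 0.5,
                         resample = c("auto", "all", "none")) {
    resample <- match.arg(resample)
    F <- .tract_fibers(f, step, resample)
    G <- .tract_fibers(g, step, resample)
    r <- cpp_tract_similarity(F, G)
    pairs <- data.frame(i = r$pairs[, 1], j = r$pairs[, 2])
    .fa_over_relation(F, G, pairs, field)
}
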