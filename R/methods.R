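#' @include AllClasses.R AllGenerics.R
NULL

# ---- constructors -----------------------------------------------------------

#' Construct a TensorField
#'
#' @param tensors array `(nx, ny, nz, 6)`, component order xx, yy, zz, xy,
#'   xz, yz; or `(nx, ny, nz)` of zeros for an empty field.
#' @param voxelSize mm per axis (length 3 or scalar, recycled).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(voxelSize)` with origin zero (voxel centers at integer indices).
#' @param flags optional logical array marking degenerate-fit voxels.
#' @return a [TensorField-class] with its FA map computed and cached.
#' @examples
#' tens <- array(0, c(4, 4, 4, 6))
#' tens[, , , 1:3] <- 7e-4   # isotropic field
#' f <- tensorField(tens, voxelSize = 2)
#' range(faMap(f))
#' @export
tensorField <- function(tensors, voxelSize = c(1, 1, 1), affine = NULL,
                        flags = NULL) {
    voxelSize <- rep_len(as.numeric(voxelSize), 3L)
    d <- dim(tensors)
    if (is.null(affine)) {
        affine <- diag(c(voxelSize, 1))
    }
    nvox <- prod(d[1:3])
    fa <- array(cpp_fa_tensors(matrix(tensors, nrow = nvox, ncol = 6L)), d[1:3])
    if (is.null(flags)) flags <- array(FALSE, d[1:3])
    new("TensorField", tensors = tensors, voxelSize = voxelSize,
        affine = affine, fa = fa, flags = flags)
}

#' Construct a Fiber
#'
#' @param points numeric matrix of world-mm points (rows) with 3 columns.
#' @param provenance list recording method, seed and parameters.
#' @return a [Fiber-class].
#' @export
fiber <- function(points, provenance = list()) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    dimnames(points) <- NULL
    new("Fiber", points = points, provenance = provenance)
}

#' Construct a FiberTract
#'
#' @param fibers list of [Fiber-class] objects (or point matrices, which
#'   are wrapped).
#' @param provenance list (method, ROI pair, thresholds, padding used).
#' @return a [FiberTract-class].
#' @export
fiberTract <- function(fibers = list(), provenance = list()) {
    fibers <- lapply(fibers, function(f) if (is(f, "Fiber")) f else fiber(f))
    new("FiberTract", fibers = fibers, provenance = provenance)
}

#' Deterministic-tracker parameters
#'
#' @param stepLength propagation step, mm.
#' @param faThreshold FA termination threshold.
#' @param maxSteps maximum steps per propagation direction.
#' @param seedDensity seeds per voxel axis (d places a d^3 sub-grid).
#' @return a [TrackingParams-class].
#' @export
trackingParams <- function(stepLength = 0.5, faThreshold = 0.25,
                           maxSteps = 2000, seedDensity = 1) {
    new("TrackingParams", stepLength = stepLength, faThreshold = faThreshold,
        maxSteps = maxSteps, seedDensity = seedDensity)
}

#' Global-search parameters
#'
#' @param faThreshold minimum FA at sampled points.
#' @param faFallback threshold retried when the search fails outright.
#' @param bendingAngle maximum bending angle between adjacent segments, deg.
#' @param avgStep target mean neighbor step length, mm.
#' @param epsilon cost floor per mm (admissible-heuristic scale).
#' @param offsetSet `"74"` (default) or the finer `"98"` neighbor set.
#' @param maxExpansions state-expansion cap per start node.
#' @return a [GSParams-class].
#' @export
gsParams <- function(faThreshold = 0.3, faFallback = 0.15, bendingAngle = 60,
                     avgStep = 2, epsilon = 1e-3, offsetSet = "74",
                     maxExpansions = 2e6) {
    new("GSParams", faThreshold = faThreshold, faFallback = faFallback,
        bendingAngle = bendingAngle, avgStep = avgStep, epsilon = epsilon,
        offsetSet = offsetSet, maxExpansions = maxExpansions)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn faMap cached FA map of the field.
#' @export
setMethod("faMap", "TensorField", function(x) x@fa)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TensorField", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("affineMat", "TensorField", function(x) x@affine)

#' Grid dimensions of a tensor field
#' @param x a [TensorField-class].
#' @export
setMethod("dim", "TensorField", function(x) dim(x@tensors)[1:3])

#' @rdname fiberPoints
#' @export
setMethod("fiberPoints", "Fiber", function(x) x@points)

#' @rdname fiberPoints
#' @export
setMethod("arcLength", "Fiber", function(x) {
    p <- x@points
    c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
})

#' @rdname fiberPoints
#' @export
setMethod("fibers", "FiberTract", function(x) x@fibers)

#' @rdname fiberPoints
#' @export
setMethod("nFibers", "FiberTract", function(x) length(x@fibers))

#' Number of fibers in a tract
#' @param x a [FiberTract-class].
#' @export
setMethod("length", "FiberTract", function(x) length(x@fibers))

#' Extract a single fiber
#' @param x a [FiberTract-class].
#' @param i fiber index.
#' @export
setMethod("[[", "FiberTract", function(x, i) x@fibers[[i]])

#' @rdname fiberPoints
#' @export
setMethod("provenance", "Fiber", function(x) x@provenance)

#' @rdname fiberPoints
#' @export
setMethod("provenance", "FiberTract", function(x) x@provenance)

#' @rdname sAvg
#' @export
setMethod("sAvg", "SimilarityReport", function(x) x@sAvg)

#' @rdname sAvg
#' @export
setMethod("sMin", "SimilarityReport", function(x) x@sMin)

# ---- show -------------------------------------------------------------------

setMethod("show", "TensorField", function(object) {
    d <- dim(object)
    cat(sprintf("TensorField: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
                d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
                object@voxelSize[3]))
    cat(sprintf("  FA range [%.3f, %.3f]; %d flagged voxels\n",
                min(object@fa), max(object@fa), sum(object@flags)))
})

setMethod("show", "Fiber", function(object) {
    al <- arcLength(object)
    cat(sprintf("Fiber: %d points, %.1f mm", nrow(object@points),
                al[length(al)]))
    if (!is.null(object@provenance$method))
        cat(sprintf(" [%s]", object@provenance$method))
    cat("\n")
})

setMethod("show", "FiberTract", function(object) {
    cat(sprintf("FiberTract: %d fibers", length(object@fibers)))
    if (!is.null(object@provenance$method))
        cat(sprintf(" [%s]", object@provenance$method))
    if (!is.null(object@provenance$faThreshold))
        cat(sprintf(", FA threshold %.3g", object@provenance$faThreshold))
    cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s, %d x %d x %d voxels @ %.3g mm, SNR %.3g\n",
                object@kind, object@dims[1], object@dims[2], object@dims[3],
                object@voxelSize[1], object@snr))
})

setMethod("show", "PhantomDataset", function(object) {
    d <- dim(object@dwi)
    cat(sprintf("PhantomDataset: %s phantom, %d x %d x %d x %d DWI, SNR %.3g\n",
                object@spec@kind, d[1], d[2], d[3], d[4], object@spec@snr))
    cat(sprintf("  ROI sizes %d / %d voxels; %d centerline curve(s)\n",
                sum(object@roiA), sum(object@roiB), length(object@bundle@curves)))
})

setMethod("show", "SearchGrid", function(object) {
    cat(sprintf("SearchGrid: %d x %d x %d nodes, spacing %.3g mm, %d offsets\n",
                object@dims[1], object@dims[2], object@dims[3],
                object@spacing, nrow(object@offsets)))
    rng <- range(object@offLen)
    cat(sprintf("  step lengths %.2f-%.2f mm (mean %.2f)\n",
                rng[1], rng[2], mean(object@offLen)))
})

setMethod("show", "SimilarityReport", function(object) {
    cat(sprintf("SimilarityReport: s_avg %.3f mm, s_min %.3f mm over %d pairs\n",
                object@sAvg, object@sMin, object@nPairs))
    if (!is.na(object@faF))
        cat(sprintf("  mean FA %.3f / %.3f (%d points outside field)\n",
                    object@faF, object@faG, object@nOutside))
})
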