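#' @include AllClasses.R
NULL

#' Per-voxel fractional anisotropy map of a tensor field
#'
#' @param x a [TensorField-class].
#' @return numeric array with the grid dimensions of `x`, values in [0, 1].
#' @export
setGeneric("faMap", function(x) standardGeneric("faMap"))

#' Voxel geometry accessors
#'
#' `voxelSize` returns the mm extent per axis; `affineMat` the 4x4
#' voxel-to-world matrix (0-based voxel indices map to world mm).
#'
#' @param x a [TensorField-class].
#' @return `voxelSize`: numeric length 3; `affineMat`: 4x4 matrix.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setGeneric("affineMat", function(x) standardGeneric("affineMat"))

#' Fiber and tract accessors
#'
#' `fiberPoints` returns the point matrix of a fiber; `arcLength` its
#' cumulative arc length per point; `fibers` the fiber list of a tract;
#' `nFibers` the fiber count; `provenance` the provenance record.
#'
#' @param x a [Fiber-class] or [FiberTract-class].
#' @export
setGeneric("fiberPoints", function(x) standardGeneric("fiberPoints"))

#' @rdname fiberPoints
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname fiberPoints
#' @export
setGeneric("fibers", function(x) standardGeneric("fibers"))

#' @rdname fiberPoints
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))

#' @rdname fiberPoints
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Similarity report accessors
#'
#' @param x a [SimilarityReport-class].
#' @export
setGeneric("sAvg", function(x) standardGeneric("sAvg"))

#' @rdname sAvg
#' @export
setGeneric("sMin", function(x) standardGeneric("sMin"))
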