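#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TensorField: a regular grid of symmetric diffusion tensors
#'
#' Stores the six unique tensor components per voxel as an array of
#' dimension `c(nx, ny, nz, 6)` (component order xx, yy, zz, xy, xz, yz),
#' together with the voxel geometry.  Voxel centers sit at integer 0-based
#' indices under the affine; world coordinates are millimetres.  A
#' fractional-anisotropy map is computed once at construction and cached.
#'
#' @slot tensors four-dimensional numeric array, last dimension length 6.
#' @slot voxelSize numeric length 3, mm per axis (strictly positive).
#' @slot affine invertible 4x4 voxel-to-world matrix (0-based indices).
#' @slot fa cached per-voxel FA array, `dim = dim(tensors)[1:3]`.
#' @slot flags logical array marking voxels where the tensor fit was
#'   degenerate (non-positive signal) and the zero tensor was stored.
#'
#' @seealso [tensorField()], [fitTensors()], [faMap()]
#' @export
setClass("TensorField",
    representation(tensors = "array", voxelSize = "numeric",
                   affine = "matrix", fa = "array", flags = "array"))

setValidity("TensorField", function(object) {
    d <- dim(object@tensors)
    if (length(d) != 4L || d[4] != 6L)
        return("tensors must be an (nx, ny, nz, 6) array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        return("voxel sizes must be three strictly positive values")
    if (!all(dim(object@affine) == c(4L, 4L)))
        return("affine must be 4x4")
    detA <- det(object@affine[1:3, 1:3])
    if (!is.finite(detA) || abs(detA) < 1e-12)
        return("affine must be invertible")
    if (!all(dim(object@fa) == d[1:3]))
        return("FA cache dimensions do not match the tensor grid")
    if (!all(dim(object@flags) == d[1:3]))
        return("flags dimensions do not match the tensor grid")
    # FA cache must match recomputation; spot-check a bounded subsample
    nvox <- prod(d[1:3])
    idx <- if (nvox > 512L) round(seq(1L, nvox, length.out = 512L)) else seq_len(nvox)
    tm <- matrix(object@tensors, nrow = nvox, ncol = 6L)[idx, , drop = FALSE]
    if (max(abs(cpp_fa_tensors(tm) - as.vector(object@fa)[idx])) > 1e-9)
        return("FA cache does not match recomputation from tensors")
    TRUE
})

#' Fiber: an ordered 3D polyline in world millimetres
#'
#' @slot points numeric matrix, one row per point, columns x, y, z (mm).
#' @slot provenance list recording method, seed and parameters.
#'
#' @seealso [fiber()], [arcLength()], [FiberTract-class]
#' @export
setClass("Fiber",
    representation(points = "matrix", provenance = "list"))

setValidity("Fiber", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L || nrow(p) < 2L)
        return("a fiber needs at least 2 points with 3 coordinates each")
    if (any(!is.finite(p)))
        return("fiber points must be finite")
    seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(seg == 0))
        return("consecutive fiber points must be distinct")
    TRUE
})

#' FiberTract: a set of fibers with shared provenance
#'
#' @slot fibers list of [Fiber-class] objects.
#' @slot provenance list (method, ROI pair, thresholds, padding used, seed).
#'
#' @seealso [fiberTract()], [runTracker()], [reconstructPathway()]
#' @export
setClass("FiberTract",
    representation(fibers = "list", provenance = "list"))

setValidity("FiberTract", function(object) {
    if (!all(vapply(object@fibers, is, logical(1), "Fiber")))
        return("all elements of fibers must be Fiber objects")
    TRUE
})

#' PhantomSpec: parameters of a DTI software phantom
#'
#' Defaults emulate a clinical 1.5 T protocol: b = 1000 s/mm^2, the
#' six-direction oblique double-gradient scheme, 2 mm isotropic voxels,
#' prolate bundle tensors with eigenvalues (1.7e-3, 3e-4, 3e-4) mm^2/s
#' (plateau FA ~ 0.75) over an isotropic background of 7e-4 mm^2/s.
#'
#' @slot kind one of "straight", "branching", "kissing", "spiral".
#' @slot tubeRadius bundle tube radius, mm.
#' @slot length straight-segment / trunk+arm length, mm.
#' @slot branchAngle per-arm branching angle, degrees.
#' @slot kissRadius circular-arc radius of the kissing configuration, mm.
#' @slot spiralTurns number of spiral turns (> 3 for kind "spiral").
#' @slot spiralR0,spiralREnd outer and inner spiral radius, mm.
#' @slot voxelSize voxel size per axis, mm.
#' @slot dims volume dimensions, voxels.
#' @slot bValue diffusion weighting, s/mm^2.
#' @slot gradients unit gradient directions, one per row.
#' @slot snr target signal-to-noise ratio S0 / sigma on the b0 image.
#' @slot lambdaBundle prolate eigenvalues inside the bundle.
#' @slot isoDiffusivity background isotropic diffusivity.
#' @slot s0 non-diffusion-weighted signal level (arbitrary units).
#' @slot seed integer seed for the noise generator.
#'
#' @seealso [phantomSpec()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
    representation(kind = "character", tubeRadius = "numeric",
                   length = "numeric", branchAngle = "numeric",
                   kissRadius = "numeric", spiralTurns = "numeric",
                   spiralR0 = "numeric", spiralREnd = "numeric",
                   voxelSize = "numeric", dims = "integer",
                   bValue = "numeric", gradients = "matrix",
                   snr = "numeric", lambdaBundle = "numeric",
                   isoDiffusivity = "numeric", s0 = "numeric",
                   seed = "numeric"))

setValidity("PhantomSpec", function(object) {
    if (!object@kind %in% c("straight", "branching", "kissing", "spiral"))
        return("kind must be straight, branching, kissing or spiral")
    if (object@kind == "spiral" && object@spiralTurns <= 3)
        return("a spiral phantom must have more than three turns")
    if (object@snr <= 0)
        return("snr must be positive")
    if (object@tubeRadius < min(object@voxelSize))
        return("tube radius must be at least one voxel")
    if (any(sqrt(rowSums(object@gradients^2)) - 1 > 1e-8))
        return("gradient directions must be unit vectors")
    TRUE
})

#' GroundTruthBundle: phantom centerlines with tangents and tube radius
#'
#' @slot curves list of lists, each with `points` (dense world-mm polyline)
#'   and `tangents` (unit tangent per point).
#' @slot radius tube radius, mm.
#'
#' @seealso [buildGeometry()]
#' @export
setClass("GroundTruthBundle",
    representation(curves = "list", radius = "numeric"))

setValidity("GroundTruthBundle", function(object) {
    for (cv in object@curves) {
        tg <- cv$tangents
        if (nrow(tg) != nrow(cv$points))
            return("each curve needs one tangent per point")
        if (nrow(tg) > 1L) {
            dots <- rowSums(tg[-1L, , drop = FALSE] * tg[-nrow(tg), , drop = FALSE])
            if (any(dots < cos(30 * pi / 180)))
                return("consecutive tangents must change by less than 30 degrees")
        }
    }
    TRUE
})

#' PhantomDataset: simulated DWI with ground truth
#'
#' @slot dwi noisy DWI stack, array `(nx, ny, nz, nvol)`.
#' @slot dwiClean noiseless DWI stack.
#' @slot bvals,bvecs per-volume b-values (s/mm^2) and gradient directions.
#' @slot trueField the rasterized ground-truth [TensorField-class].
#' @slot bundle the [GroundTruthBundle-class].
#' @slot roiA,roiB logical voxel masks marking the two endpoint regions.
#' @slot spec the generating [PhantomSpec-class].
#'
#' @seealso [buildPhantom()]
#' @export
setClass("PhantomDataset",
    representation(dwi = "array", dwiClean = "array", bvals = "numeric",
                   bvecs = "matrix", trueField = "TensorField",
                   bundle = "GroundTruthBundle", roiA = "array",
                   roiB = "array", spec = "PhantomSpec"))

setValidity("PhantomDataset", function(object) {
    if (any(object@roiA & object@roiB))
        return("roi_a and roi_b must be disjoint")
    if (!any(object@roiA) || !any(object@roiB))
        return("both ROIs must be non-empty")
    TRUE
})

#' TrackingParams: deterministic-tracker settings
#'
#' @slot stepLength propagation step, mm (default 0.5).
#' @slot faThreshold termination threshold on FA (default 0.25).
#' @slot maxSteps maximum steps per propagation direction (default 2000).
#' @slot seedDensity seeds per voxel axis (d gives d^3 seeds per voxel).
#'
#' @seealso [trackingParams()], [runTracker()]
#' @export
setClass("TrackingParams",
    representation(stepLength = "numeric", faThreshold = "numeric",
                   maxSteps = "numeric", seedDensity = "numeric"))

setValidity("TrackingParams", function(object) {
    if (object@stepLength <= 0) return("step length must be positive")
    if (object@faThreshold < 0 || object@faThreshold >= 1)
        return("fa threshold must lie in [0, 1)")
    TRUE
})

#' GSParams: global-search settings
#'
#' @slot faThreshold minimum FA at sampled points (default 0.3).
#' @slot faFallback threshold retried after a failed search (default 0.15).
#' @slot bendingAngle maximum bending angle between adjacent segments, deg.
#' @slot avgStep target mean neighbor step length, mm (default 2).
#' @slot epsilon cost floor per mm; keeps the A* heuristic admissible.
#' @slot offsetSet "74" (default) or the finer "98" neighbor set.
#' @slot maxExpansions search-effort cap per start node.
#'
#' @seealso [gsParams()], [reconstructPathway()]
#' @export
setClass("GSParams",
    representation(faThreshold = "numeric", faFallback = "numeric",
                   bendingAngle = "numeric", avgStep = "numeric",
                   epsilon = "numeric", offsetSet = "character",
                   maxExpansions = "numeric"))

setValidity("GSParams", function(object) {
    if (object@bendingAngle <= 0 || object@bendingAngle > 90)
        return("bending angle limit must lie in (0, 90] degrees")
    if (!object@offsetSet %in% c("74", "98"))
        return("offsetSet must be \"74\" or \"98\"")
    TRUE
})

#' SearchGrid: the structured lattice searched by the global method
#'
#' @slot origin world-mm position of lattice node (0, 0, 0).
#' @slot spacing lattice spacing, mm (chosen so the mean neighbor step
#'   equals the configured average step).
#' @slot dims lattice dimensions.
#' @slot offsets integer neighbor offsets, one per row (centrally
#'   symmetric, zero excluded; 74 by default).
#' @slot offDirs unit direction per offset.
#' @slot offLen step length per offset, mm.
#' @slot bbox optional 2x3 world-mm bounding box (rows lo, hi) or NULL.
#'
#' @seealso [buildGrid()], [neighborOffsets()]
#' @export
setClass("SearchGrid",
    representation(origin = "numeric", spacing = "numeric", dims = "integer",
                   offsets = "matrix", offDirs = "matrix", offLen = "numeric",
                   bbox = "matrixOrNULL"))

setValidity("SearchGrid", function(object) {
    off <- object@offsets
    if (any(rowSums(abs(off)) == 0)) return("offset set must exclude zero")
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    if (!setequal(key(off), key(-off)))
        return("offset set must be centrally symmetric")
    if (object@spacing <= 0) return("spacing must be positive")
    TRUE
})

#' SimilarityReport: tract-pair similarity summary
#'
#' @slot sAvg mean trimmed closest-fiber distance over the relation, mm.
#' @slot sMin distance of the closest fiber pair, mm.
#' @slot nPairs number of (deduplicated) closest fiber pairs.
#' @slot faF,faG average FA per tract over trimmed, correlated fibers
#'   (NA when no tensor field was supplied).
#' @slot pairs data.frame of the fiber-pair relation with distances.
#' @slot nOutside number of fiber points outside the tensor field that
#'   were excluded from the FA averages.
#'
#' @seealso [tractSimilarity()], [faSimilarity()]
#' @export
setClass("SimilarityReport",
    representation(sAvg = "numeric", sMin = "numeric", nPairs = "integer",
                   faF = "numeric", faG = "numeric", pairs = "data.frame",
                   nOutside = "integer"))

setValidity("SimilarityReport", function(object) {
    if (object@sMin > object@sAvg + 1e-12) return("s_min must not exceed s_avg")
    if (object@sAvg < 0 || object@sMin < 0) return("distances must be non-negative")
    if (object@nPairs < 1L) return("at least one fiber pair is required")
    TRUE
})
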