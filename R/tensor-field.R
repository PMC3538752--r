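#' @include methods.R
NULL

# world <-> voxel transforms (0-based voxel indices at voxel centers)
.voxel2world <- function(affine, ijk) {
    ijk <- rbind(t(cbind(ijk)), 1)
    t(affine %*% ijk)[, 1:3, drop = FALSE]
}

.world2voxel <- function(affine, xyz) {
    xyz <- rbind(t(cbind(xyz)), 1)
    t(solve(affine) %*% xyz)[, 1:3, drop = FALSE]
}

#' The six-direction oblique double-gradient encoding scheme
#'
#' Unit gradient directions (+-1, 1, 0), (+-1, 0, 1), (0, 1, +-1) / sqrt(2),
#' as used with single-shell b = 1000 s/mm^2 clinical DTI.
#'
#' @return 6 x 3 matrix of unit vectors.
#' @export
obliqueGradients <- function() {
    g <- rbind(c(1, 1, 0), c(-1, 1, 0), c(1, 0, 1),
               c(-1, 0, 1), c(0, 1, 1), c(0, 1, -1))
    g / sqrt(2)
}

# design matrix for the log-linear model ln S = ln S0 - b g' D g
.dti_design <- function(bvals, bvecs) {
    g <- bvecs
    cbind(1,
          -bvals * g[, 1]^2,
          -bvals * g[, 2]^2,
          -bvals * g[, 3]^2,
          -2 * bvals * g[, 1] * g[, 2],
          -2 * bvals * g[, 1] * g[, 3],
          -2 * bvals * g[, 2] * g[, 3])
}

#' Fit diffusion tensors from a DWI stack
#'
#' Per-voxel log-linear least squares of the single-tensor signal model
#' `S_k = S0 * exp(-b_k g_k' D g_k)`.  Requires at least one b = 0 volume
#' and at least six non-collinear gradient directions (the design matrix
#' must have full rank 7).  Voxels with any non-positive signal get the
#' zero tensor and are flagged.
#'
#' @param dwi array `(nx, ny, nz, nvol)`.
#' @param bvals numeric, b-value per volume, s/mm^2.
#' @param bvecs matrix `nvol x 3`, unit gradient per volume (the b = 0 rows
#'   may be zero).
#' @param voxelSize mm per axis.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return a [TensorField-class]; degenerate voxels carry `TRUE` in the
#'   field's flags.
#' @examples
#' g <- obliqueGradients()
#' D <- c(1.7e-3, 3e-4, 3e-4, 0, 0, 0)
#' q <- g[, 1]^2 * D[1] + g[, 2]^2 * D[2] + g[, 3]^2 * D[3]
#' s <- c(1000, 1000 * exp(-1000 * q))
#' dwi <- array(rep(s, each = 8), c(2, 2, 2, 7))
#' f <- fitTensors(dwi, c(0, rep(1000, 6)), rbind(0, g))
#' f@tensors[1, 1, 1, ]
#' @export
fitTensors <- function(dwi, bvals, bvecs, voxelSize = c(1, 1, 1),
                       affine = NULL) {
    d <- dim(dwi)
    if (length(d) != 4L)
        stop("dwi must be a 4D array (x, y, z, volume)")
    nvol <- d[4]
    bvecs <- as.matrix(bvecs)
    if (length(bvals) != nvol || nrow(bvecs) != nvol)
        stop("bvals/bvecs must match the number of DWI volumes")
    if (!any(bvals == 0))
        stop("at least one b = 0 reference volume is required")
    if (sum(bvals > 0) < 6L)
        stop("at least 6 diffusion-weighted volumes are required")
    B <- .dti_design(bvals, bvecs)
    if (qr(B)$rank < 7L)
        stop("fewer than 6 independent gradient directions")
    P <- solve(crossprod(B), t(B))          # 7 x nvol pseudoinverse

    nvox <- prod(d[1:3])
    S <- matrix(dwi, nrow = nvox, ncol = nvol)
    ok <- rowSums(S <= 0) == 0L
    tens <- matrix(0, nvox, 6L)
    if (any(ok)) {
        beta <- log(S[ok, , drop = FALSE]) %*% t(P)
        tens[ok, ] <- beta[, 2:7, drop = FALSE]
    }
    tensorField(array(tens, c(d[1:3], 6L)), voxelSize = voxelSize,
                affine = affine, flags = array(!ok, d[1:3]))
}

#' Eigen-decomposition of diffusion tensors
#'
#' @param x length-6 tensor (xx, yy, zz, xy, xz, yz) or an `N x 6` matrix.
#' @return for a single tensor, a list with `values` (descending) and
#'   `vectors` (columns e1, e2, e3); for a matrix, a list with an `N x 3`
#'   value matrix and a `3 x 3 x N` vector array.  Eigenvector signs are
#'   unconstrained (sign coherence is the trackers' job).
#' @examples
#' tensorEigen(c(3, 2, 1, 0, 0, 0))$values
#' @export
tensorEigen <- function(x) {
    single <- is.null(dim(x))
    m <- if (single) matrix(x, 1L) else as.matrix(x)
    if (ncol(m) != 6L) stop("tensors need 6 components")
    if (any(!is.finite(m))) stop("tensor components must be finite")
    e <- cpp_eigen_tensors(m)
    if (single)
        list(values = drop(e$values), vectors = matrix(e$vectors, 3L, 3L))
    else
        list(values = e$values, vectors = array(e$vectors, c(3L, 3L, nrow(m))))
}

#' Fractional anisotropy from eigenvalues
#'
#' The normalized eigenvalue-deviation measure
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clipped to
#' [0, 1].  Negative eigenvalues beyond tolerance are clamped to zero
#' (standard practice for noisy low-direction fits) and flagged via the
#' `"clamped"` attribute.  An all-zero spectrum returns 0 by convention.
#'
#' @param lambda numeric length 3 (any order) or an `N x 3` matrix.
#' @return FA value(s) in [0, 1].
#' @examples
#' fractionalAnisotropy(c(1, 1, 1))   # 0
#' fractionalAnisotropy(c(1, 0, 0))   # 1
#' fractionalAnisotropy(c(2, 1, 1))   # 0.40825
#' @export
fractionalAnisotropy <- function(lambda) {
    m <- if (is.null(dim(lambda))) matrix(lambda, 1L) else as.matrix(lambda)
    clamped <- rowSums(m < -1e-12) > 0L
    m[m < 0] <- 0
    ss <- rowSums(m^2)
    mu <- rowMeans(m)
    fa <- sqrt(1.5 * rowSums((m - mu)^2) / ifelse(ss > 0, ss, 1))
    fa[ss == 0] <- 0
    fa <- pmin(pmax(fa, 0), 1)
    if (is.null(dim(lambda))) fa <- fa[[1L]]
    if (any(clamped)) attr(fa, "clamped") <- clamped
    fa
}

#' Westin shape coefficients of a tensor ellipsoid
#'
#' `cl = (l1 - l2)/l1`, `cp = (l2 - l3)/l1`, `cs = l3/l1`; the shape class
#' is the largest coefficient, ties broken in the order linear > planar >
#' spherical.  A non-positive l1 leaves the shape undefined: spherical is
#' returned with the `"undefined"` attribute set.
#'
#' @param lambda eigenvalues, descending, length 3.
#' @return list with `cl`, `cp`, `cs` and `shapeClass`.
#' @examples
#' westinShape(c(2, 2, 1))$shapeClass   # planar by tie-break
#' @export
westinShape <- function(lambda) {
    l1 <- lambda[1]; l2 <- lambda[2]; l3 <- lambda[3]
    if (l1 <= 0) {
        out <- list(cl = 0, cp = 0, cs = 1, shapeClass = "spherical")
        attr(out, "undefined") <- TRUE
        return(out)
    }
    cl <- (l1 - l2) / l1
    cp <- (l2 - l3) / l1
    cs <- l3 / l1
    shapeClass <- if (cl >= cp && cl >= cs) "linear"
                  else if (cp >= cs) "planar"
                  else "spherical"
    list(cl = cl, cp = cp, cs = cs, shapeClass = shapeClass)
}

#' Trilinearly interpolate a tensor field at world-mm points
#'
#' Component-wise trilinear interpolation of the six unique components from
#' the eight surrounding voxel centers.  Points outside the center-to-center
#' domain yield `NA` rows and `FALSE` in the `"inside"` attribute (trackers
#' treat that as termination).
#'
#' @param field a [TensorField-class].
#' @param points world-mm coordinates, length 3 or `N x 3`.
#' @return length-6 tensor or `N x 6` matrix, with attribute `"inside"`.
#' @export
interpolateTensor <- function(field, points) {
    single <- is.null(dim(points))
    pm <- if (single) matrix(points, 1L) else as.matrix(points)
    r <- cpp_interp_tensor(field@tensors, dim(field), solve(field@affine), pm)
    out <- if (single) drop(r$tensors) else r$tensors
    attr(out, "inside") <- r$inside
    out
}

#' Interpolated FA at world-mm points
#'
#' @param field a [TensorField-class].
#' @param points world-mm coordinates, length 3 or `N x 3`.
#' @return FA of the interpolated tensor per point; `NA` outside the field.
#' @export
interpolateFA <- function(field, points) {
    t6 <- interpolateTensor(field, points)
    m <- if (is.null(dim(t6))) matrix(t6, 1L) else t6
    fa <- rep(NA_real_, nrow(m))
    inside <- attr(t6, "inside")
    if (any(inside))
        fa[inside] <- cpp_fa_tensors(m[inside, , drop = FALSE])
    if (is.null(dim(t6))) fa <- fa[[1L]]
    fa
}

# ---- NIfTI / text I/O -------------------------------------------------------

#' Read a DWI dataset from NIfTI plus FSL-style bval/bvec files
#'
#' @param dwiPath path to a 4D NIfTI volume.
#' @param bvalPath,bvecPath FSL-style text files (`bvec` holds three rows
#'   x, y, z).
#' @return list with `dwi` (4D array), `bvals`, `bvecs`, `voxelSize`,
#'   `affine`.
#' @export
readDWI <- function(dwiPath, bvalPath, bvecPath) {
    img <- RNifti::readNifti(dwiPath)
    bvals <- scan(bvalPath, quiet = TRUE)
    bv <- as.matrix(read.table(bvecPath))
    if (nrow(bv) == 3L) bv <- t(bv)
    dimnames(bv) <- NULL
    affine <- rbind(RNifti::xform(img), c(0, 0, 0, 1))[1:4, 1:4]
    list(dwi = unclass(img)[, , , , drop = FALSE], bvals = bvals, bvecs = bv,
         voxelSize = sqrt(colSums(affine[1:3, 1:3]^2)),   # column norms
         affine = affine)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file with non-zero voxels marking the region.
#' @return logical array.
#' @export
readMask <- function(path) {
    img <- RNifti::readNifti(path)
    array(unclass(img) != 0, dim(img)[1:3])
}

.write_nifti <- function(arr, path, voxelSize, affine) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep_len(voxelSize, min(length(dim(arr)), 3L))
    RNifti::sform(img) <- structure(affine, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write a tensor field as NIfTI
#'
#' Writes the six-component tensor volume and, alongside it, an FA map
#' (suffix `_fa`).
#'
#' @param field a [TensorField-class].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @return the tensor path, invisibly.
#' @export
writeTensorField <- function(field, path) {
    .write_nifti(field@tensors, path, field@voxelSize, field@affine)
    faPath <- sub("(\\.nii(\\.gz)?)$", "_fa\\1", path)
    .write_nifti(field@fa, faPath, field@voxelSize, field@affine)
    invisible(path)
}
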