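#' @include methods.R utils.R tensor-field.R
NULL

#' Specify a DTI software phantom
#'
#' Geometry defaults follow a clinically plausible protocol: 2 mm isotropic
#' voxels, 64^3 volumes (48 x 48 in-plane, 16 slices for the planar
#' spiral), prolate bundle eigenvalues (1.7e-3, 3e-4, 3e-4) mm^2/s giving
#' a plateau FA of about 0.80, and an isotropic background of 7e-4 mm^2/s.
#' The straight, branching and kissing bundles are thick (6 mm tube
#' radius), like the major pathways whose character they share (pyramidal
#' and optic tracts); the spiral is thin (2 mm), like strongly curved
#' pathways with cortical terminations.  The spiral is an inward
#' Archimedean spiral with 3.5 turns from radius 30 mm down to 6 mm and a
#' thin 2 mm tube: the voxel-scale tube keeps the anisotropic channel
#' barely resolved (partial-volume borders, noisy core), while the 2.9 mm
#' of isotropic background between adjacent turns stays below any usable
#' FA threshold — the strong-curvature challenge that pathways with
#' cortical terminations pose at clinical resolution.
#'
#' @param kind phantom type.
#' @param tubeRadius tube radius, mm; `NULL` picks the per-kind default
#'   (6 mm, but 2 mm for the spiral).
#' @param length straight length / branching trunk+arm length, mm.
#' @param branchAngle per-arm branching angle, degrees.
#' @param kissRadius arc radius of the kissing configuration, mm.
#' @param spiralTurns,spiralR0,spiralREnd spiral turn count and outer/inner
#'   radii, mm.
#' @param voxelSize voxel size, mm (scalar or length 3).
#' @param dims volume dimensions in voxels; defaults depend on `kind`.
#' @param bValue diffusion weighting, s/mm^2.
#' @param gradients unit gradient directions (default: the six-direction
#'   oblique double-gradient scheme).
#' @param snr target SNR (`S0 / sigma` on the b0 image); the protocol of
#'   interest simulates 15 and 30.
#' @param lambdaBundle prolate eigenvalues inside the bundle.
#' @param isoDiffusivity background isotropic diffusivity.
#' @param s0 b0 signal level.
#' @param seed noise seed.
#' @return a [PhantomSpec-class].
#' @examples
#' phantomSpec("spiral", snr = 30)
#' @export
phantomSpec <- function(kind = c("straight", "branching", "kissing", "spiral"),
                        tubeRadius = NULL, length = 60, branchAngle = 40,
                        kissRadius = 30, spiralTurns = 3.5, spiralR0 = 30,
                        spiralREnd = 6, voxelSize = 2, dims = NULL,
                        bValue = 1000, gradients = obliqueGradients(),
                        snr = 30, lambdaBundle = c(1.7e-3, 3e-4, 3e-4),
                        isoDiffusivity = 7e-4, s0 = 1000, seed = 1) {
    kind <- match.arg(kind)
    if (is.null(dims))
        dims <- if (kind == "spiral") c(48L, 48L, 16L) else c(64L, 64L, 64L)
    if (is.null(tubeRadius))
        tubeRadius <- if (kind == "spiral") 2 else 6
    new("PhantomSpec", kind = kind, tubeRadius = tubeRadius, length = length,
        branchAngle = branchAngle, kissRadius = kissRadius,
        spiralTurns = spiralTurns, spiralR0 = spiralR0,
        spiralREnd = spiralREnd, voxelSize = rep_len(as.numeric(voxelSize), 3L),
        dims = as.integer(dims), bValue = bValue, gradients = gradients,
        snr = snr, lambdaBundle = lambdaBundle,
        isoDiffusivity = isoDiffusivity, s0 = s0, seed = seed)
}

# volume center in world mm (voxel centers at integer indices, origin 0)
.volume_center <- function(spec) spec@voxelSize * (spec@dims - 1L) / 2

# finite-difference unit tangents of a polyline
.tangents_of <- function(points) {
    n <- nrow(points)
    tg <- matrix(0, n, 3L)
    tg[1L, ] <- points[2L, ] - points[1L, ]
    tg[n, ] <- points[n, ] - points[n - 1L, ]
    if (n > 2L)
        tg[2:(n - 1L), ] <- points[3:n, , drop = FALSE] -
            points[1:(n - 2L), , drop = FALSE]
    tg / sqrt(rowSums(tg^2))
}

# arc turning from direction d0 to d1 in the xy-plane with a given radius
.turn_arc <- function(start, d0, angleDeg, radius, ds) {
    phi <- angleDeg * pi / 180
    n <- max(2L, ceiling(abs(phi) * radius / ds))
    a <- seq(0, phi, length.out = n + 1L)[-1L]
    th0 <- atan2(d0[2], d0[1])
    # center is 90 deg to the left (positive angle) or right of travel
    sgn <- sign(phi)
    cen <- start[1:2] + radius * c(cos(th0 + sgn * pi / 2), sin(th0 + sgn * pi / 2))
    ang0 <- atan2(start[2] - cen[2], start[1] - cen[1])
    pts <- cbind(cen[1] + radius * cos(ang0 + a),
                 cen[2] + radius * sin(ang0 + a),
                 start[3])
    pts
}

#' Build phantom centerline geometry
#'
#' Centerlines are dense world-mm polylines (arc-length sampled at a
#' quarter voxel) with unit tangents.  The branching phantom is a trunk
#' splitting into two arms (smooth 10 mm turn radius at the bifurcation);
#' the kissing phantom is two circular arcs meeting tangentially at one
#' point; the spiral is a planar inward Archimedean spiral
#' `r(theta) = r0 - k*theta` over more than three turns.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [GroundTruthBundle-class].  Errors if the geometry exits the
#'   volume.
#' @export
buildGeometry <- function(spec) {
    ds <- min(spec@voxelSize) / 4
    ctr <- .volume_center(spec)
    curves <- switch(spec@kind,
        straight = {
            x <- seq(-spec@length / 2, spec@length / 2, by = ds)
            if (x[length(x)] < spec@length / 2) x <- c(x, spec@length / 2)
            list(cbind(ctr[1] + x, ctr[2], ctr[3]))
        },
        branching = {
            # trunk along x, then a smooth turn into each straight arm
            trunkLen <- spec@length / 2
            armLen <- spec@length / 2
            rTurn <- 10
            start <- c(ctr[1] - spec@length * 0.5, ctr[2], ctr[3])
            xs <- seq(0, trunkLen, by = ds)
            trunk <- cbind(start[1] + xs, start[2], start[3])
            bp <- trunk[nrow(trunk), ]
            mk_arm <- function(sgn) {
                arc <- .turn_arc(bp, c(1, 0, 0), sgn * spec@branchAngle, rTurn, ds)
                dir <- c(cos(spec@branchAngle * pi / 180),
                         sgn * sin(spec@branchAngle * pi / 180), 0)
                tail <- arc[nrow(arc), ]
                arcLen <- rTurn * spec@branchAngle * pi / 180
                rest <- max(armLen - arcLen, 10)
                ls <- seq(ds, rest, by = ds)
                straight <- cbind(tail[1] + ls * dir[1], tail[2] + ls * dir[2],
                                  tail[3])
                rbind(trunk, arc, straight)
            }
            list(mk_arm(1), mk_arm(-1))
        },
        kissing = {
            # two arcs of radius R touching tangentially at the volume center
            R <- spec@kissRadius
            phiMax <- 50 * pi / 180
            phi <- seq(-phiMax, phiMax, by = ds / R)
            if (phi[length(phi)] < phiMax) phi <- c(phi, phiMax)
            up <- cbind(ctr[1] + R * sin(phi), ctr[2] + R * (1 - cos(phi)),
                        ctr[3])
            down <- cbind(ctr[1] + R * sin(phi), ctr[2] - R * (1 - cos(phi)),
                          ctr[3])
            list(up, down)
        },
        spiral = {
            turns <- spec@spiralTurns
            k <- (spec@spiralR0 - spec@spiralREnd) / (2 * pi * turns)
            thMax <- 2 * pi * turns
            # dense parametric sampling, then arc-length resampling
            th <- seq(0, thMax, length.out = ceiling(thMax * spec@spiralR0 / ds))
            r <- spec@spiralR0 - k * th
            pts <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3])
            list(.resample_polyline(pts, ds))
        })
    curves <- lapply(curves, function(p) {
        p <- .resample_polyline(p, ds)
        list(points = p, tangents = .tangents_of(p))
    })
    lo <- -spec@voxelSize / 2
    hi <- spec@voxelSize * (spec@dims - 0.5)
    for (cv in curves) {
        rng <- apply(cv$points, 2L, range)
        if (any(rng[1, ] < lo) || any(rng[2, ] > hi))
            stop("phantom geometry exits the volume; enlarge dims or shrink it")
    }
    new("GroundTruthBundle", curves = curves, radius = spec@tubeRadius)
}

#' Rasterize a bundle into a ground-truth tensor field
#'
#' Voxels within the tube radius of a centerline get a prolate tensor with
#' the principal axis along the local tangent; where tubes overlap
#' (kissing, branching, adjacent spiral turns) the contributing prolate
#' tensors are averaged component-wise, mirroring the partial-volume
#' averaging that defeats single-tensor trackers at crossings.  Background
#' voxels are isotropic.
#'
#' @param bundle a [GroundTruthBundle-class].
#' @param spec the generating [PhantomSpec-class].
#' @return a [TensorField-class].
#' @export
rasterizeTensors <- function(bundle, spec) {
    dims <- spec@dims
    affine <- diag(c(spec@voxelSize, 1))
    centers <- .voxel_centers(dims, affine)
    nvox <- nrow(centers)
    lam <- spec@lambdaBundle
    l23 <- mean(lam[2:3])
    acc <- matrix(0, nvox, 6L)
    cnt <- integer(nvox)
    for (cv in bundle@curves) {
        pd <- cpp_polyline_distance(centers, cv$points)
        inTube <- pd$distance <= bundle@radius
        if (!any(inTube)) next
        tg <- cv$tangents[pd$nearest[inTube], , drop = FALSE]
        d1 <- lam[1] - l23
        acc[inTube, 1] <- acc[inTube, 1] + d1 * tg[, 1]^2 + l23
        acc[inTube, 2] <- acc[inTube, 2] + d1 * tg[, 2]^2 + l23
        acc[inTube, 3] <- acc[inTube, 3] + d1 * tg[, 3]^2 + l23
        acc[inTube, 4] <- acc[inTube, 4] + d1 * tg[, 1] * tg[, 2]
        acc[inTube, 5] <- acc[inTube, 5] + d1 * tg[, 1] * tg[, 3]
        acc[inTube, 6] <- acc[inTube, 6] + d1 * tg[, 2] * tg[, 3]
        cnt[inTube] <- cnt[inTube] + 1L
    }
    bg <- cnt == 0L
    tens <- acc / pmax(cnt, 1L)
    tens[bg, 1:3] <- spec@isoDiffusivity
    tens[bg, 4:6] <- 0
    tensorField(array(tens, c(dims, 6L)), voxelSize = spec@voxelSize,
                affine = affine)
}

#' Simulate a noiseless DWI stack from a tensor field
#'
#' One b = 0 volume at constant `S0` plus one volume per gradient with
#' `S = S0 * exp(-b g' D g)`.
#'
#' @param field a [TensorField-class].
#' @param spec a [PhantomSpec-class] (b-value, gradients, S0).
#' @return list with `dwi` (4D array), `bvals`, `bvecs`.
#' @export
simulateDWI <- function(field, spec) {
    g <- spec@gradients
    if (any(abs(sqrt(rowSums(g^2)) - 1) > 1e-8))
        stop("gradient directions must be unit vectors")
    d <- dim(field)
    nvox <- prod(d)
    tm <- matrix(field@tensors, nvox, 6L)
    vols <- matrix(spec@s0, nvox, nrow(g) + 1L)
    for (i in seq_len(nrow(g))) {
        q <- g[i, 1]^2 * tm[, 1] + g[i, 2]^2 * tm[, 2] + g[i, 3]^2 * tm[, 3] +
            2 * g[i, 1] * g[i, 2] * tm[, 4] + 2 * g[i, 1] * g[i, 3] * tm[, 5] +
            2 * g[i, 2] * g[i, 3] * tm[, 6]
        vols[, i + 1L] <- spec@s0 * exp(-spec@bValue * q)
    }
    list(dwi = array(vols, c(d, nrow(g) + 1L)),
         bvals = c(0, rep(spec@bValue, nrow(g))),
         bvecs = rbind(c(0, 0, 0), g))
}

#' Add Rician noise to a DWI stack
#'
#' Each value `v` is replaced by `sqrt((v + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma = s0/snr`
#' (SNR defined on the b0 image, matching MR magnitude statistics).  With a
#' fixed seed the underlying Gaussian draws are identical across SNR
#' levels, differing only by the sigma scaling.
#'
#' @param images DWI array.
#' @param snr target signal-to-noise ratio, > 0.
#' @param s0 reference signal level.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return noisy array of the same shape.
#' @export
addRicianNoise <- function(images, snr, s0 = 1000, seed = NULL) {
    stopifnot(snr > 0)
    sigma <- s0 / snr
    if (!is.null(seed)) set.seed(seed)
    n <- length(images)
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    array(sqrt((images + sigma * z1)^2 + (sigma * z2)^2), dim(images))
}

#' Place end ROIs on a phantom bundle
#'
#' Each ROI is a one-voxel-thick slab of voxels centered on a centerline
#' endpoint, extending beyond the tube radius laterally so it covers the
#' full tube cross-section.  For the branching phantom `roiB` covers both
#' leaf endpoints; for the spiral `roiA` sits at the outer end and `roiB`
#' at the inner end.
#'
#' @param bundle a [GroundTruthBundle-class].
#' @param spec the [PhantomSpec-class].
#' @return list with logical masks `roiA` and `roiB`.
#' @export
placeROIs <- function(bundle, spec) {
    dims <- spec@dims
    affine <- diag(c(spec@voxelSize, 1))
    centers <- .voxel_centers(dims, affine)
    slab <- function(endPoint, tangent) {
        ax <- which.max(abs(tangent))
        lat <- setdiff(1:3, ax)
        m <- abs(centers[, ax] - endPoint[ax]) <= spec@voxelSize[ax] / 2 &
            sqrt((centers[, lat[1]] - endPoint[lat[1]])^2 +
                 (centers[, lat[2]] - endPoint[lat[2]])^2) <=
                spec@tubeRadius + max(spec@voxelSize)
        array(m, dims)
    }
    ends <- function(cv, which) {
        n <- nrow(cv$points)
        if (which == "first") list(p = cv$points[1L, ], t = cv$tangents[1L, ])
        else list(p = cv$points[n, ], t = cv$tangents[n, ])
    }
    cv1 <- bundle@curves[[1L]]
    a <- ends(cv1, "first")
    roiA <- slab(a$p, a$t)
    if (spec@kind == "branching") {
        roiB <- array(FALSE, dims)
        for (cv in bundle@curves) {
            b <- ends(cv, "last")
            roiB <- roiB | slab(b$p, b$t)
        }
    } else {
        b <- ends(cv1, "last")
        roiB <- slab(b$p, b$t)
    }
    overlap <- roiA & roiB
    if (any(overlap)) stop("end ROIs overlap; phantom too small")
    list(roiA = roiA, roiB = roiB)
}

#' Generate a complete phantom dataset
#'
#' Builds the centerline geometry, rasterizes the ground-truth tensor
#' field, simulates the DWI stack, adds Rician noise at the spec's SNR and
#' places the end ROIs.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomDataset-class].
#' @examples
#' pd <- buildPhantom(phantomSpec("straight", dims = c(40, 16, 16)))
#' pd
#' @export
buildPhantom <- function(spec) {
    bundle <- buildGeometry(spec)
    field <- rasterizeTensors(bundle, spec)
    sim <- simulateDWI(field, spec)
    noisy <- addRicianNoise(sim$dwi, spec@snr, s0 = spec@s0, seed = spec@seed)
    rois <- placeROIs(bundle, spec)
    new("PhantomDataset", dwi = noisy, dwiClean = sim$dwi, bvals = sim$bvals,
        bvecs = sim$bvecs, trueField = field, bundle = bundle,
        roiA = rois$roiA, roiB = rois$roiB, spec = spec)
}

#' Fit a tensor field from a phantom's (noisy) DWI
#'
#' @param pd a [PhantomDataset-class].
#' @param noiseless use the noiseless stack instead.
#' @return a [TensorField-class].
#' @export
phantomField <- function(pd, noiseless = FALSE) {
    dwi <- if (noiseless) pd@dwiClean else pd@dwi
    fitTensors(dwi, pd@bvals, pd@bvecs, voxelSize = pd@spec@voxelSize,
               affine = pd@trueField@affine)
}

#' Write a phantom dataset to disk
#'
#' NIfTI volumes (noisy DWI, b0, FA of the ground-truth field, both ROI
#' masks), FSL-style bval/bvec text files, the centerlines as a streamline
#' file and the spec as JSON.
#'
#' @param pd a [PhantomDataset-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
writePhantom <- function(pd, dir, prefix = pd@spec@kind) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vs <- pd@spec@voxelSize
    aff <- pd@trueField@affine
    p <- function(x) file.path(dir, paste0(prefix, x))
    .write_nifti(pd@dwi, p("_dwi.nii.gz"), vs, aff)
    .write_nifti(pd@dwi[, , , 1L], p("_b0.nii.gz"), vs, aff)
    .write_nifti(faMap(pd@trueField), p("_fa.nii.gz"), vs, aff)
    .write_nifti(pd@roiA + 0, p("_roiA.nii.gz"), vs, aff)
    .write_nifti(pd@roiB + 0, p("_roiB.nii.gz"), vs, aff)
    writeLines(paste(pd@bvals, collapse = " "), p(".bval"))
    write.table(t(pd@bvecs), p(".bvec"), row.names = FALSE,
                col.names = FALSE)
    ctr <- fiberTract(lapply(pd@bundle@curves, function(cv) cv$points),
                      provenance = list(method = "ground-truth"))
    writeFibers(ctr, p("_centerlines.trk"), affine = aff)
    spec <- pd@spec
    sl <- sapply(slotNames(spec), function(s) slot(spec, s), simplify = FALSE)
    jsonlite::write_json(sl, p("_spec.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
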