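test_that("noiseless DWI fit recovers the generating tensor", {
    g <- obliqueGradients()
    D <- c(1.7e-3, 3e-4, 3e-4, 0, 0, 0)
    q <- g[, 1]^2 * D[1] + g[, 2]^2 * D[2] + g[, 3]^2 * D[3]
    s <- c(1000, 1000 * exp(-1000 * q))
    dwi <- array(rep(s, each = 8), c(2, 2, 2, 7))
    f <- fitTensors(dwi, c(0, rep(1000, 6)), rbind(0, g))
    expect_lt(max(abs(f@tensors[1, 1, 1, ] - D)), 1e-12)
    expect_false(any(f@flags))
})

test_that("fit roundtrip holds for random SPD tensors incl. off-diagonals", {
    set.seed(7)
    g <- obliqueGradients()
    bvals <- c(0, rep(1000, 6))
    bvecs <- rbind(0, g)
    for (r in 1:50) {
        D <- random_spd_tensor()
        q <- g[, 1]^2 * D[1] + g[, 2]^2 * D[2] + g[, 3]^2 * D[3] +
            2 * g[, 1] * g[, 2] * D[4] + 2 * g[, 1] * g[, 3] * D[5] +
            2 * g[, 2] * g[, 3] * D[6]
        s <- c(1000, 1000 * exp(-1000 * q))
        dwi <- array(rep(s, each = 1), c(1, 1, 1, 7))
        f <- fitTensors(dwi, bvals, bvecs)
        expect_lt(max(abs(f@tensors[1, 1, 1, ] - D)), 1e-10)
    }
})

test_that("degenerate DWI cases fit to the zero tensor or raise errors", {
    g <- obliqueGradients()
    # all volumes equal to b0 -> zero tensor
    dwi <- array(500, c(2, 2, 1, 7))
    f <- fitTensors(dwi, c(0, rep(1000, 6)), rbind(0, g))
    expect_equal(max(abs(f@tensors)), 0)
    # isotropic signal -> FA 0
    q <- rep(7e-4, 6)
    s <- c(1000, 1000 * exp(-1000 * q))
    dwi <- array(rep(s, each = 1), c(1, 1, 1, 7))
    f <- fitTensors(dwi, c(0, rep(1000, 6)), rbind(0, g))
    expect_lt(faMap(f)[1, 1, 1], 1e-12)
    # non-positive signal -> flagged zero tensor
    dwi[1, 1, 1, 3] <- 0
    f <- fitTensors(dwi, c(0, rep(1000, 6)), rbind(0, g))
    expect_true(f@flags[1, 1, 1])
    expect_equal(max(abs(f@tensors)), 0)
    # collinear gradients -> configuration error
    gg <- g[c(1, 1, 1, 2, 3, 4), ]
    expect_error(fitTensors(array(s, c(1, 1, 1, 7)), c(0, rep(1000, 6)),
                            rbind(0, gg)), "independent")
    expect_error(fitTensors(array(500, c(2, 2, 1, 7)), c(0, rep(1000, 5)),
                            rbind(0, g)), "match")
})

test_that("eigendecomposition orders values and recovers known rotations", {
    e <- tensorEigen(c(3, 2, 1, 0, 0, 0))
    expect_equal(e$values, c(3, 2, 1))
    expect_equal(abs(e$vectors[, 1]), c(1, 0, 0), tolerance = 1e-12)

    e <- tensorEigen(c(2, 2, 2, 0, 0, 0))
    expect_equal(e$values, c(2, 2, 2))
    expect_equal(crossprod(e$vectors), diag(3), tolerance = 1e-9)

    set.seed(11)
    for (r in 1:20) {
        R <- qr.Q(qr(matrix(rnorm(9), 3)))
        D <- R %*% diag(c(3, 2, 1)) %*% t(R)
        e <- tensorEigen(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]))
        expect_equal(e$values, c(3, 2, 1), tolerance = 1e-9)
        for (a in 1:3)   # eigenvectors equal R's columns up to sign
            expect_equal(abs(sum(e$vectors[, a] * R[, a])), 1, tolerance = 1e-9)
    }
    expect_error(tensorEigen(c(1, NA, 1, 0, 0, 0)), "finite")
})

test_that("fractional anisotropy matches hand values and its invariances", {
    expect_equal(fractionalAnisotropy(c(1, 1, 1)), 0)
    expect_equal(fractionalAnisotropy(c(1, 0, 0)), 1)
    expect_equal(fractionalAnisotropy(c(2, 1, 1)), 0.40825, tolerance = 1e-5)
    # independent formulation: sqrt(3/2) * ||lam - mean|| / ||lam||
    set.seed(3)
    for (r in 1:50) {
        lam <- sort(runif(3, 1e-4, 3e-3), decreasing = TRUE)
        ref <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
        expect_equal(fractionalAnisotropy(lam), ref, tolerance = 1e-12)
        # scale invariance
        expect_equal(fractionalAnisotropy(lam * 7.3),
                     fractionalAnisotropy(lam), tolerance = 1e-12)
    }
    # rotation invariance through the tensor route
    set.seed(4)
    for (r in 1:20) {
        t6 <- random_spd_tensor()
        e <- tensorEigen(t6)
        R <- qr.Q(qr(matrix(rnorm(9), 3)))
        D <- matrix(c(t6[1], t6[4], t6[5], t6[4], t6[2], t6[6],
                      t6[5], t6[6], t6[3]), 3)
        Dr <- R %*% D %*% t(R)
        er <- tensorEigen(c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2],
                            Dr[1, 3], Dr[2, 3]))
        expect_equal(fractionalAnisotropy(er$values),
                     fractionalAnisotropy(e$values), tolerance = 1e-9)
    }
    # clamped negatives are flagged
    fa <- fractionalAnisotropy(c(1, 0.5, -0.2))
    expect_true(any(attr(fa, "clamped")))
    expect_equal(fractionalAnisotropy(c(0, 0, 0)), 0)
})

test_that("Westin shape coefficients classify with the stated tie-breaks", {
    s <- westinShape(c(1, 1, 1))
    expect_equal(c(s$cl, s$cp, s$cs), c(0, 0, 1))
    expect_equal(s$shapeClass, "spherical")
    s <- westinShape(c(1, 0, 0))
    expect_equal(c(s$cl, s$cp, s$cs), c(1, 0, 0))
    expect_equal(s$shapeClass, "linear")
    s <- westinShape(c(2, 2, 1))        # planar-spherical tie -> planar
    expect_equal(c(s$cl, s$cp, s$cs), c(0, 0.5, 0.5))
    expect_equal(s$shapeClass, "planar")
    s <- westinShape(c(2, 1, 0))        # linear-planar tie -> linear
    expect_equal(s$shapeClass, "linear")
    s <- westinShape(c(0, 0, 0))
    expect_equal(s$shapeClass, "spherical")
    expect_true(attr(s, "undefined"))
    # partition of unity over random spectra
    set.seed(5)
    for (r in 1:30) {
        lam <- sort(runif(3, 1e-5, 3e-3), decreasing = TRUE)
        s <- westinShape(lam)
        expect_equal(s$cl + s$cp + s$cs, 1, tolerance = 1e-9)
        expect_true(all(c(s$cl, s$cp, s$cs) >= 0))
    }
})

test_that("trilinear interpolation matches the 8-corner weighted sum", {
    f <- homogeneous_field(dims = c(3, 3, 3), voxelSize = 1)
    expect_equal(drop(interpolateTensor(f, c(1.3, 0.7, 1.9))),
                 f@tensors[1, 1, 1, ], tolerance = 1e-12, ignore_attr = TRUE)

    tens <- array(0, c(2, 2, 2, 6))
    tens[, , , 1:3] <- 1e-3
    tens[2, 1, 1, 1] <- 3e-3
    tens[1, 2, 1, 4] <- 5e-4
    fld <- tensorField(tens, voxelSize = 2)
    set.seed(6)
    for (r in 1:20) {
        p <- runif(3, 0, 2)           # world mm inside the 2 mm cell
        v <- p / 2                    # voxel coords
        w <- c((1 - v[1]) * (1 - v[2]) * (1 - v[3]), v[1] * (1 - v[2]) * (1 - v[3]),
               (1 - v[1]) * v[2] * (1 - v[3]), v[1] * v[2] * (1 - v[3]),
               (1 - v[1]) * (1 - v[2]) * v[3], v[1] * (1 - v[2]) * v[3],
               (1 - v[1]) * v[2] * v[3], v[1] * v[2] * v[3])
        corners <- rbind(tens[1, 1, 1, ], tens[2, 1, 1, ], tens[1, 2, 1, ],
                         tens[2, 2, 1, ], tens[1, 1, 2, ], tens[2, 1, 2, ],
                         tens[1, 2, 2, ], tens[2, 2, 2, ])
        expect_equal(drop(interpolateTensor(fld, p)), drop(w %*% corners),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
    # voxel centers return the stored tensor exactly
    expect_identical(as.vector(drop(interpolateTensor(fld, c(2, 0, 2)))[1:6]),
                     tens[2, 1, 2, ])
    # outside the center-to-center domain -> NA with inside = FALSE
    out <- interpolateTensor(fld, c(-0.5, 0, 0))
    expect_true(all(is.na(out)))
    expect_false(attr(out, "inside"))
})

test_that("midpoint interpolation is the component average", {
    tens <- array(0, c(2, 1, 1, 6))
    tens[1, 1, 1, ] <- c(2, 1, 1, 0, 0, 0)
    tens[2, 1, 1, ] <- c(4, 1, 1, 0, 0, 0)
    fld <- tensorField(tens, voxelSize = 1)
    expect_equal(drop(interpolateTensor(fld, c(0.5, 0, 0)))[1], 3)
})

test_that("tensor field NIfTI roundtrip preserves data and geometry", {
    f <- homogeneous_field(dims = c(6, 5, 4), voxelSize = c(2, 2, 2.5))
    path <- tempfile(fileext = ".nii.gz")
    writeTensorField(f, path)
    img <- RNifti::readNifti(path)
    expect_equal(dim(img), c(6L, 5L, 4L, 6L))
    expect_equal(unclass(img)[3, 2, 1, ], f@tensors[3, 2, 1, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
    faPath <- sub("\\.nii\\.gz$", "_fa.nii.gz", path)
    expect_true(file.exists(faPath))
    fa <- RNifti::readNifti(faPath)
    expect_equal(unclass(fa)[1, 1, 1], faMap(f)[1, 1, 1], tolerance = 1e-6,
                 ignore_attr = TRUE)
})
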