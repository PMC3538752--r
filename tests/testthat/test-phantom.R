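test_that("straight geometry is a uniformly sampled axis-aligned segment", {
    spec <- phantomSpec("straight", dims = c(40, 16, 16))
    b <- buildGeometry(spec)
    expect_length(b@curves, 1L)
    p <- b@curves[[1]]$points
    expect_equal(sqrt(sum((p[nrow(p), ] - p[1, ])^2)), 60)
    tg <- b@curves[[1]]$tangents
    expect_true(all(abs(tg[, 1] - 1) < 1e-12))
    expect_lte(max(diff(c(0, cumsum(sqrt(rowSums(diff(p)^2)))))), 0.5 + 1e-9)
})

test_that("spiral geometry turns by its configured angle", {
    # the total turning of an Archimedean spiral equals turns * 360 degrees
    spec <- phantomSpec("spiral", spiralR0 = 25, spiralREnd = 6,
                        dims = c(48, 48, 16))
    b <- buildGeometry(spec)
    p <- b@curves[[1]]$points
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    dots <- pmin(1, pmax(-1, rowSums(seg[-1, ] * seg[-nrow(seg), ])))
    turning <- sum(acos(dots)) * 180 / pi
    expect_equal(turning, 3.5 * 360, tolerance = 0.01)
    # outer end first, inner end last
    ctr <- spec@voxelSize * (spec@dims - 1) / 2
    expect_gt(sqrt(sum((p[1, 1:2] - ctr[1:2])^2)), 20)
    expect_lt(sqrt(sum((p[nrow(p), 1:2] - ctr[1:2])^2)), 8)
})

test_that("branching geometry has a trunk endpoint and two leaf endpoints", {
    b <- buildGeometry(phantomSpec("branching"))
    expect_length(b@curves, 2L)
    starts <- sapply(b@curves, function(cv) cv$points[1, ])
    expect_equal(starts[, 1], starts[, 2])   # shared trunk endpoint
    leaves <- sapply(b@curves, function(cv) cv$points[nrow(cv$points), ])
    expect_gt(sqrt(sum((leaves[, 1] - leaves[, 2])^2)), 10)
    # smoothness: consecutive tangent change below 30 degrees everywhere
    for (cv in b@curves) {
        tg <- cv$tangents
        dots <- rowSums(tg[-1, ] * tg[-nrow(tg), ])
        expect_gt(min(dots), cos(30 * pi / 180))
    }
})

test_that("geometry that exits the volume is refused", {
    expect_error(buildGeometry(phantomSpec("straight", dims = c(16, 16, 16))),
                 "exits the volume")
})

test_that("rasterized tensors are prolate in-tube, isotropic outside, planar at crossings", {
    spec <- tiny_straight()
    b <- buildGeometry(spec)
    fld <- rasterizeTensors(b, spec)
    fa <- faMap(fld)
    ctr <- round((spec@dims - 1) / 2) + 1
    faExpected <- fractionalAnisotropy(spec@lambdaBundle)
    inTube <- fa[8:24, ctr[2], ctr[3]]
    expect_equal(max(abs(inTube - faExpected)), 0, tolerance = 1e-9)
    expect_lt(sd(inTube), 1e-9)          # constant plateau
    expect_equal(fa[1, 1, 1], 0)         # background isotropic
    expect_equal(fld@tensors[1, 1, 1, 1:3], rep(spec@isoDiffusivity, 3))

    # equal-lambda orthogonal crossing averages to a planar tensor
    lam <- spec@lambdaBundle
    l23 <- mean(lam[2:3])
    tx <- c(lam[1], l23, l23, 0, 0, 0)
    ty <- c(l23, lam[1], l23, 0, 0, 0)
    e <- tensorEigen((tx + ty) / 2)
    s <- westinShape(e$values)
    expect_equal(s$shapeClass, "planar")
    expect_gt(s$cp, s$cl)
})

test_that("simulated DWI follows the single-tensor signal model", {
    spec <- tiny_straight()
    fld <- rasterizeTensors(buildGeometry(spec), spec)
    sim <- simulateDWI(fld, spec)
    expect_equal(dim(sim$dwi)[4], 7L)
    expect_equal(max(abs(sim$dwi[, , , 1] - spec@s0)), 0)   # b0 volume
    # hand value: D = diag(1.7e-3, 3e-4, 3e-4), g = (1,1,0)/sqrt(2), b = 1000
    g <- matrix(c(1, 1, 0) / sqrt(2), 1)
    spec2 <- phantomSpec("straight", dims = c(32, 12, 12), length = 40,
                         tubeRadius = 4, gradients = g)
    fld2 <- homogeneous_field(dims = c(2, 2, 2), lambda = c(1.7e-3, 3e-4, 3e-4))
    sim2 <- simulateDWI(fld2, spec2)
    expect_equal(sim2$dwi[1, 1, 1, 2] / spec2@s0, exp(-1), tolerance = 1e-12)
    # isotropic tensors attenuate identically for every gradient
    iso <- isotropic_field(dims = c(2, 2, 2), d = 7e-4)
    simIso <- simulateDWI(iso, phantomSpec("straight", dims = c(32, 12, 12),
                                           length = 40))
    atten <- simIso$dwi[1, 1, 1, -1]
    expect_equal(max(abs(atten - 1000 * exp(-1000 * 7e-4))), 0,
                 tolerance = 1e-9)
    bad <- phantomSpec("straight", dims = c(32, 12, 12), length = 40)
    bad@gradients <- matrix(c(1, 1, 0), 1)
    expect_error(simulateDWI(iso, bad), "unit")
})

test_that("Rician noise has the stated magnitude statistics and determinism", {
    img <- array(0, c(25, 25, 20))       # background: pure Rayleigh noise
    noisy <- addRicianNoise(img, snr = 30, s0 = 1000, seed = 9)
    sigmaHat <- sqrt(mean(noisy^2) / 2)  # Rayleigh: E[v^2] = 2 sigma^2
    expect_equal(sigmaHat, 1000 / 30, tolerance = 0.05)
    # determinism
    expect_identical(addRicianNoise(img, 30, 1000, seed = 9), noisy)
    # vanishing-noise limit
    img2 <- array(500, c(4, 4, 4))
    expect_equal(addRicianNoise(img2, snr = 1e9, s0 = 1000, seed = 1), img2,
                 tolerance = 1e-6 * 1000)
    # same seed, different SNR: identical Gaussian draws, scaled sigma
    out15 <- addRicianNoise(img2, 15, 1000, seed = 4)
    set.seed(4)
    z1 <- rnorm(length(img2)); z2 <- rnorm(length(img2))
    sg <- 1000 / 15
    expect_equal(as.vector(out15),
                 sqrt((as.vector(img2) + sg * z1)^2 + (sg * z2)^2),
                 tolerance = 1e-12)
})

test_that("end ROIs are disjoint slabs covering the tube cross-section", {
    spec <- tiny_straight()
    pd <- buildPhantom(spec)
    expect_false(any(pd@roiA & pd@roiB))
    expect_gt(sum(pd@roiA), 0)
    expect_gt(sum(pd@roiB), 0)
    # every in-tube voxel in the slab plane belongs to the mask
    centers <- gstract:::.voxel_centers(spec@dims, pd@trueField@affine)
    d <- gstract:::cpp_polyline_distance(centers,
                                         pd@bundle@curves[[1]]$points)$distance
    endA <- pd@bundle@curves[[1]]$points[1, ]
    slabPlane <- abs(centers[, 1] - endA[1]) <= spec@voxelSize[1] / 2
    inTube <- d <= spec@tubeRadius
    expect_true(all(pd@roiA[array(slabPlane & inTube, spec@dims)]))
    # both ROIs intersect high-FA tube voxels
    fa <- faMap(pd@trueField)
    expect_gt(max(fa[pd@roiA]), 0.5)
    expect_gt(max(fa[pd@roiB]), 0.5)
    # branching: roiB covers both leaves
    pdb <- buildPhantom(phantomSpec("branching", snr = 30, seed = 2))
    leaves <- sapply(pdb@bundle@curves, function(cv) cv$points[nrow(cv$points), ])
    for (i in 1:2)
        expect_true(gstract:::.points_in_mask(matrix(leaves[, i], 1),
                                              pdb@roiB, pdb@trueField@affine))
})

test_that("noiseless simulate-fit roundtrip reproduces the rasterized field", {
    pd <- buildPhantom(tiny_straight())
    fitted <- phantomField(pd, noiseless = TRUE)
    expect_lt(max(abs(fitted@tensors - pd@trueField@tensors)), 1e-10)
})

test_that("phantom datasets are reproducible from their seed", {
    a <- buildPhantom(tiny_straight(seed = 5))
    b <- buildPhantom(tiny_straight(seed = 5))
    expect_identical(a@dwi, b@dwi)
    c <- buildPhantom(tiny_straight(seed = 6))
    expect_false(identical(a@dwi, c@dwi))
})

test_that("phantom spec validity constraints hold", {
    expect_error(phantomSpec("spiral", spiralTurns = 2.5), "three turns")
    expect_error(phantomSpec("straight", snr = -1), "snr")
    expect_error(phantomSpec("straight", tubeRadius = 0.5), "voxel")
})
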