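test_that("resampling yields equal spacing on the input polyline", {
    seg <- cbind(seq(0, 10, length.out = 41), 0, 0)
    out <- resampleFiber(seg, 0.5)
    expect_equal(nrow(out), 21L)
    expect_equal(max(abs(diff(out[, 1]) - 0.5)), 0, tolerance = 1e-12)
    # already uniform input is unchanged
    expect_equal(resampleFiber(out, 0.5), out, tolerance = 1e-9)
    # L-shaped polyline: points stay on the polyline, length preserved
    L <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0))
    r <- resampleFiber(L, 0.7)
    onPoly <- apply(r, 1, function(p)
        (abs(p[2]) < 1e-9 && p[1] >= -1e-9 && p[1] <= 5 + 1e-9) ||
        (abs(p[1] - 5) < 1e-9 && p[2] >= -1e-9 && p[2] <= 5 + 1e-9))
    expect_true(all(onPoly))
    alen <- sum(sqrt(rowSums(diff(r)^2)))
    expect_equal(alen, 10, tolerance = 0.7)
    expect_equal(r[1, ], c(0, 0, 0))
    expect_equal(r[nrow(r), ], c(5, 5, 0))
    expect_error(resampleFiber(matrix(0, 1, 3)), "degenerate")
})

test_that("closest-point pairs deduplicate and match brute force", {
    a <- cbind(0:5 * 1.0, 0, 0)
    r <- closestPointPairs(a, a)
    expect_equal(nrow(r$pairs), 6L)                 # (p, p) once per point
    expect_equal(max(r$distance), 0)
    b <- cbind(0:5 * 1.0, 1, 0)
    r <- closestPointPairs(a, b)
    expect_equal(nrow(r$pairs), 6L)                 # bidirectional matches agree
    expect_equal(unique(r$distance), 1)
    # T-shaped configuration: many-to-one matches collapse
    stem <- cbind(0, seq(1, 5, 1), 0)
    bar <- cbind(seq(-2, 2, 1), 0, 0)
    r <- closestPointPairs(bar, stem)
    expect_lt(nrow(r$pairs), nrow(bar) + nrow(stem))
    key <- sort(paste(r$pairs[, 1], r$pairs[, 2]))
    expect_equal(key, oracle_point_relation(bar, stem))
})

test_that("mean closest distance matches hand and brute-force values", {
    a <- cbind(0:10 * 1.0, 0, 0)
    expect_equal(meanClosestDistance(a, a), 0)
    b <- cbind(0:10 * 1.0, 1, 0)
    expect_equal(meanClosestDistance(a, b), 1)
    fi <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
    fj <- rbind(c(0, 1, 0), c(2, 1, 0))
    expect_equal(meanClosestDistance(fi, fj), oracle_mcd(fi, fj))
    # symmetric by construction
    set.seed(31)
    for (r in 1:10) {
        A <- random_fiber(8); B <- random_fiber(6)
        expect_equal(meanClosestDistance(A, B), meanClosestDistance(B, A))
        expect_equal(meanClosestDistance(A, B), oracle_mcd(A, B))
    }
})

test_that("trimming removes pure overhang and spares diverging fibers", {
    core <- cbind(seq(0, 20, 0.5), 0, 0)
    ext <- cbind(seq(-5, 25, 0.5), 0.2, 0)    # overhangs 5 mm at both ends
    tp <- trimPair(core, ext)
    expect_equal(nrow(tp$a), nrow(core))      # fi untouched
    expect_equal(tp$removed[1], 0)
    expect_equal(tp$removed[2], 10, tolerance = 1)   # ~5 mm per end
    expect_equal(range(tp$b[, 1]), c(0, 20), tolerance = 0.5)
    # identical fibers: unchanged
    tp <- trimPair(core, core)
    expect_equal(tp$removed, c(0, 0))
    # shared mid-section, diverging at both ends: neither trimmed
    th <- seq(-1, 1, length.out = 41)
    f1 <- cbind(th * 10, 5 * pmax(0, abs(th) - 0.5)^2 * 40, 0)
    f2 <- cbind(th * 10, -5 * pmax(0, abs(th) - 0.5)^2 * 40, 0)
    tp <- trimPair(f1, f2)
    expect_equal(tp$removed, c(0, 0))
    # orientation is resolved before trimming
    tp <- trimPair(core, ext[nrow(ext):1, ])
    expect_true(tp$reversed)
    expect_equal(tp$removed[2], 10, tolerance = 1)
    # trimming never increases the pair distance on overhang constructions
    expect_lte(gstract:::cpp_mcd_trimmed(core, ext),
               meanClosestDistance(core, ext))
})

test_that("tract similarity matches exhaustive enumeration on toy tracts", {
    f <- list(cbind(seq(0, 10, 0.5), 0, 0))
    r <- tractSimilarity(f, f)
    expect_equal(sAvg(r), 0)
    expect_equal(sMin(r), 0)
    expect_equal(r@nPairs, 1L)
    # single-fiber tracts: s_avg = s_min = trimmed mean closest distance
    g <- list(cbind(seq(0, 10, 0.5), 1, 0))
    r <- tractSimilarity(f, g)
    expect_equal(sAvg(r), 1)
    expect_equal(sMin(r), 1)
    # 2 x 2 parallel tube pairs at offsets 1 and 3 mm
    F2 <- list(cbind(seq(0, 10, 0.5), 0, 0), cbind(seq(0, 10, 0.5), 10, 0))
    G2 <- list(cbind(seq(0, 10, 0.5), 1, 0), cbind(seq(0, 10, 0.5), 13, 0))
    r <- tractSimilarity(F2, G2)
    ref <- oracle_tract_similarity(F2, G2)
    expect_equal(sAvg(r), ref$s_avg)
    expect_equal(sMin(r), ref$s_min)
    expect_equal(r@nPairs, ref$n)
    expect_equal(sAvg(r), 2)          # pairs at 1 and 3 mm
    expect_equal(sMin(r), 1)
})

test_that("tract similarity is symmetric, non-negative and min-bounded", {
    set.seed(41)
    for (rep in 1:10) {
        F <- lapply(seq_len(sample(2:4, 1)), function(i) random_fiber(12))
        G <- lapply(seq_len(sample(2:4, 1)), function(i) random_fiber(9))
        a <- tractSimilarity(F, G, resample = "none")
        b <- tractSimilarity(G, F, resample = "none")
        expect_equal(sAvg(a), sAvg(b), tolerance = 1e-12)
        expect_equal(sMin(a), sMin(b), tolerance = 1e-12)
        expect_equal(a@nPairs, b@nPairs)
        expect_gte(sMin(a), 0)
        expect_lte(sMin(a), sAvg(a))
    }
})

test_that("rigid translation shifts similarity as expected", {
    F <- list(cbind(seq(0, 20, 0.5), 0, 0), cbind(seq(0, 20, 0.5), 4, 0))
    G <- lapply(F, function(p) p + 1.5)     # translate both together
    r0 <- tractSimilarity(F, F)
    rT <- tractSimilarity(G, G)
    expect_equal(sAvg(rT), sAvg(r0), tolerance = 1e-9)
    # translating one tract perpendicular to straight fibers by delta
    Gp <- lapply(F, function(p) sweep(p, 2, c(0, 0, 0.75), "+"))
    expect_equal(sAvg(tractSimilarity(F, Gp)), 0.75, tolerance = 1e-9)
})

test_that("FA similarity averages interpolated FA over trimmed fibers", {
    f <- homogeneous_field(dims = c(21, 9, 9))
    plateau <- fractionalAnisotropy(c(1.7e-3, 3e-4, 3e-4))
    F <- list(cbind(seq(4, 36, 0.5), 8, 8))
    G <- list(cbind(seq(4, 36, 0.5), 9, 8))
    r <- faSimilarity(F, G, f)
    expect_equal(r$faF, plateau, tolerance = 1e-9)
    expect_equal(r$faG, plateau, tolerance = 1e-9)
    expect_equal(r$nOutside, 0L)
    # report fields populated through tractSimilarity
    rep <- tractSimilarity(F, G, field = f)
    expect_equal(rep@faF, plateau, tolerance = 1e-9)
    # fibers partially outside the field (no overhang, so no trimming):
    # the out-of-field points are excluded and counted
    F2 <- list(cbind(seq(-6, 36, 0.5), 8, 8))
    G2 <- list(cbind(seq(-6, 36, 0.5), 9, 8))
    r2 <- faSimilarity(F2, G2, f)
    expect_gt(r2$nOutside, 0)
})

test_that("non-uniform fibers are resampled before metrics by default", {
    # grid-bound polyline with variable spacing vs its uniform twin
    gridded <- rbind(c(0, 0, 0), c(2, 0, 0), c(4.3, 0, 0), c(6, 0, 0),
                     c(10, 0, 0))
    uniform <- cbind(seq(0, 10, 0.5), 1, 0)
    rAuto <- tractSimilarity(list(gridded), list(uniform))
    rAll <- tractSimilarity(list(gridded), list(uniform), resample = "all")
    expect_equal(sAvg(rAuto), sAvg(rAll), tolerance = 1e-9)
    expect_equal(sAvg(rAuto), 1, tolerance = 1e-6)
})
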