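test_that("dead fraction is 0 with no stain and 1 with full colocalization", {
    rc <- smallColony()
    m <- maskArray(rc$truth@mask)
    stable <- rc$truth@noiseless$stable
    zero <- array(0, dim(m))
    img0 <- VoxelImage(list(stable = stable, dead = zero),
                       voxelSize(rc$image))
    vp0 <- deadFractionProfile(img0, rc$truth@mask, rc$distmap)
    expect_true(all(vp0$dead_fraction[!is.na(vp0$dead_fraction)] == 0))
    imgF <- VoxelImage(list(stable = stable, dead = stable),
                       voxelSize(rc$image))
    vpF <- deadFractionProfile(imgF, rc$truth@mask, rc$distmap)
    expect_true(all(vpF$dead_fraction[!is.na(vpF$dead_fraction)] == 1))
})

test_that("dead-fraction profile recovers the generator's height ramp", {
    sp <- colonySpec(H = 100, R = 100,
                     deadParams = c(d0 = 20, d1 = 80, pmax = 0.3),
                     seed = 21L)
    rc <- renderColony(sp, channels = c("stable", "dead"))
    dm <- surfaceDistanceMap(rc$truth@mask)
    vp <- deadFractionProfile(rc$image, rc$truth@mask, dm)
    ok <- !is.na(vp$dead_fraction) & vp$n_stable >= 1000
    pTrue <- rampProb(vp$height_um, 20, 80, 0.3)
    expect_gt(sum(ok), 5)
    expect_true(all(abs(vp$dead_fraction[ok] - pTrue[ok]) < 0.02))
})

test_that("dead fraction is invariant under joint intensity rescaling", {
    sp <- colonySpec(H = 60, R = 60,
                     deadParams = c(d0 = 10, d1 = 50, pmax = 0.25),
                     noise = noNoise(), seed = 9L)
    rc <- renderColony(sp, channels = c("stable", "dead"))
    dm <- surfaceDistanceMap(rc$truth@mask)
    vp1 <- deadFractionProfile(rc$image, rc$truth@mask, dm)
    scaled <- VoxelImage(list(stable = getChannel(rc$image, "stable") * 7,
                              dead = getChannel(rc$image, "dead") * 7),
                         voxelSize(rc$image))
    vp2 <- deadFractionProfile(scaled, rc$truth@mask, dm)
    expect_equal(vp1$dead_fraction, vp2$dead_fraction)
})

test_that("reporter ratio fold-change is 1 for proportional channels", {
    rc <- smallColony()
    stable <- rc$truth@noiseless$stable
    img <- VoxelImage(list(stable = stable, unstable = 0.37 * stable),
                      voxelSize(rc$image))
    gr <- reporterRatioFoldChange(img, rc$truth@mask, rc$distmap,
                                  hHi = 60, hLo = 0,
                                  backgroundSubtract = FALSE)
    expect_equal(gr$fold_change, 1, tolerance = 1e-9)
})

test_that("fold-change recovers the generator's ratio doubling", {
    tall <- tallColony()   # noiseless, ratio(z) = g0 (1 + z/100)
    gr <- reporterRatioFoldChange(tall$image, tall$truth@mask, tall$distmap)
    expect_lt(abs(gr$fold_change - 2) / 2, 0.05)
    expect_error(reporterRatioFoldChange(tall$image, tall$truth@mask,
        tall$distmap, hHi = 300), "exceeds the colony height")
})

test_that("fold-change recovers the ratio slope sign under noise", {
    for (seed in c(31L, 32L, 33L)) {
        rc <- renderColony(colonySpec(H = 120, R = 120, seed = seed),
                           channels = c("stable", "unstable"))
        dm <- surfaceDistanceMap(rc$truth@mask)
        gr <- reporterRatioFoldChange(rc$image, rc$truth@mask, dm)
        expect_gt(gr$fold_change, 1)
    }
})

test_that("competition ring ratio reflects thresholded areas", {
    n <- 400
    xs <- (1:n) - n / 2
    rr <- sqrt(outer(xs^2, xs^2, "+"))
    inoc <- rr <= 30
    # only channel 1 present in the ring
    ch1 <- matrix(100, n, n); ch2 <- matrix(0, n, n)
    r1 <- competitionRingRatio(ch1, ch2, inoc, 1, ringDistance = 100,
                               ringWidth = 20, threshold = 50)
    expect_equal(r1$fraction1, 1)
    # equal half-planes: 0.5, and the fractions always sum to 1
    ch1 <- matrix(0, n, n); ch1[1:(n / 2), ] <- 100
    ch2 <- 100 - ch1
    r2 <- competitionRingRatio(ch1, ch2, inoc, 1, ringDistance = 100,
                               ringWidth = 20, threshold = 50)
    expect_equal(r2$fraction1, 0.5, tolerance = 0.02)
    expect_equal(r2$fraction1 + r2$fraction2, 1)
    expect_error(competitionRingRatio(ch1, ch2, inoc, 1,
        ringDistance = 1000), "ring")
})

test_that("competition ring recovers the generator mix fraction", {
    cp <- renderCompetition(colonySpec(mixFraction = 0.3, seed = 41L))
    cr <- competitionRingRatio(cp$ch1, cp$ch2, cp$inoculum, cp$pixelSize)
    expect_lt(abs(cr$fraction1 - 0.3), 0.02)
})

test_that("signal normalization divides and validates the denominator", {
    expect_equal(normalizeSignal(100, 4, "biovolume")$value, 25)
    expect_equal(normalizeSignal(0, 17, "od600")$value, 0)
    expect_equal(normalizeSignal(6, 2, "count_x_volume")$mode,
                 "count_x_volume")
    expect_error(normalizeSignal(5, 0, "biovolume"), "positive")
    expect_error(normalizeSignal(5, -2, "od600"), "positive")
})
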