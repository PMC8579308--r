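test_that("dome height profile follows the closed form", {
    sp <- colonySpec(H = 200, R = 400, bulgeP = 1)
    expect_equal(shapeHeight(0, sp), 200)
    expect_equal(shapeHeight(400, sp), 0)
    expect_equal(shapeHeight(100, sp), 150)     # 200 * (1 - 100/400)
    expect_equal(shapeHeight(500, sp), 0)       # clamped beyond R
    sp2 <- colonySpec(H = 100, R = 100, bulgeP = 2)
    r <- seq(0, 120, by = 0.5)
    h <- shapeHeight(r, sp2)
    expect_true(all(diff(h) <= 1e-12))          # non-increasing
    expect_error(shapeHeight(-1, sp), "non-negative")
    expect_error(colonySpec(H = -5), "positive")
    expect_error(colonySpec(R = 0), "positive")
    hemi <- colonySpec(shape = "hemisphere", H = 60, R = 60)
    expect_equal(shapeHeight(36, hemi), 48)     # 3-4-5 triangle
    expect_error(colonySpec(shape = "hemisphere", H = 50, R = 60), "H == R")
})

test_that("noise-free rendering reproduces the ground-truth fields exactly", {
    rc <- smallColony()
    img <- rc$image; tr <- rc$truth
    for (ch in channelNames(img))
        expect_identical(getChannel(img, ch), tr@noiseless[[ch]])
    m <- maskArray(tr@mask)
    # fields vanish outside the colony (beads excepted: substrate objects)
    expect_true(all(tr@noiseless$stable[!m] == 0))
    expect_true(all(tr@noiseless$unstable[!m] == 0))
    expect_true(all(!tr@deadLabel[!m]))
    # dead-stain channel mirrors the stable reporter at dead voxels
    expect_identical(tr@noiseless$dead, tr@noiseless$stable * tr@deadLabel)
})

test_that("pmax = 0 renders an empty dead-stain channel", {
    sp <- colonySpec(H = 40, R = 40, noise = noNoise(),
                     deadParams = c(d0 = 10, d1 = 30, pmax = 0), seed = 2L)
    rc <- renderColony(sp, channels = c("stable", "dead"))
    expect_true(all(getChannel(rc$image, "dead") == 0))
})

test_that("shot-noise model is mean-preserving at the stated replication", {
    set.seed(99)
    x <- array(45, c(100, 100, 1))   # + background 5 => Poisson mean 50
    noisy <- colonyvox:::.applyNoise(x,
        list(poisson_on = TRUE, read_sigma = 0, background = 5))
    expect_lt(abs(mean(noisy) - 50) / 50, 0.01)
})

test_that("mask volume converges to the solid-of-revolution volume", {
    # p = 2 dome: V = integral 2 pi r H (1 - (r/R)^2) dr = pi H R^2 / 2
    va <- pi * 40 * 40^2 / 2
    errs <- vapply(c(1, 0.5), function(v) {
        m <- renderMask(colonySpec(H = 40, R = 40, voxelSize = c(v, v, v),
                                   noise = noNoise()))
        abs(sum(maskArray(m)) * v^3 - va) / va
    }, numeric(1))
    expect_lt(errs[1], 0.01)
    expect_lte(errs[2], errs[1])
})

test_that("noiseless intensity strictly decreases with surface distance", {
    tr <- smallColony()$truth
    d <- distanceArray(tr@distance)
    sel <- !is.na(d)
    ord <- order(d[sel])
    dv <- d[sel][ord]; iv <- tr@noiseless$stable[sel][ord]
    pick <- seq(1, length(dv), length.out = 2000)
    expect_true(all(diff(iv[pick]) <= 0))
    expect_lt(iv[length(iv)], iv[1])
})

test_that("dead labels follow the height ramp at binomial accuracy", {
    tr <- smallColony()$truth
    sp <- colonySpec(H = 80, R = 80)
    m <- maskArray(tr@mask)
    d3 <- dim(m)
    zArr <- array(rep((seq_len(d3[3]) - 0.5), each = d3[1] * d3[2]), d3)
    for (zlo in c(50, 60, 70)) {
        sel <- m & zArr >= zlo & zArr < zlo + 10
        n <- sum(sel)
        p <- rampProb(zlo + 5, 50, 150, 0.3)
        phat <- mean(tr@deadLabel[sel])
        expect_lt(abs(phat - p), 4 * sqrt(max(p, 0.01) * (1 - p) / n) + 0.002)
    }
})

test_that("rendering is bitwise deterministic in the seed", {
    sp <- colonySpec(H = 30, R = 30, seed = 7L)
    a <- renderColony(sp)
    b <- renderColony(sp)
    for (ch in channelNames(a$image))
        expect_identical(getChannel(a$image, ch), getChannel(b$image, ch))
    expect_identical(a$truth@deadLabel, b$truth@deadLabel)
    c2 <- renderColony(colonySpec(H = 30, R = 30, seed = 8L))
    expect_false(identical(getChannel(a$image, "stable"),
                           getChannel(c2$image, "stable")))
})

test_that("renderMask agrees with the full render's occupancy", {
    sp <- colonySpec(H = 30, R = 30, noise = noNoise(), seed = 7L)
    expect_identical(maskArray(renderMask(sp)),
                     maskArray(renderColony(sp, "stable")$truth@mask))
})

test_that("overview scans place the requested non-overlapping footprints", {
    sp0 <- colonySpec(R = 50, H = 50, noise = noNoise(), seed = 4L)
    ov0 <- renderOverview(0, sp0)
    expect_true(all(ov0$image == 0))
    expect_equal(nrow(ov0$centers), 0)
    ov <- renderOverview(5, sp0)
    expect_equal(nrow(ov$centers), 5)
    dmat <- as.matrix(stats::dist(ov$centers))
    expect_true(all(dmat[upper.tri(dmat)] > 2 * 50))
    # single footprint area close to the analytic disk area
    ov1 <- renderOverview(1, sp0)
    expect_lt(abs(sum(ov1$image > 0) * ov1$pixelSize^2 - pi * 50^2) /
              (pi * 50^2), 0.03)
    # impossible packing fails loudly
    expect_error(renderOverview(40, sp0, fieldSize = 300), "1000 attempts")
})

test_that("competition rendering labels strains at the requested fraction", {
    sp <- colonySpec(mixFraction = 0.25, seed = 6L)
    cp <- renderCompetition(sp, inoculumRadius = 50, expansionWidth = 100)
    lab <- cp$strainLabel
    zone <- lab > 0
    expect_lt(abs(mean(lab[zone] == 1) - 0.25), 0.01)
    expect_true(all(lab[cp$inoculum] > 0))
})
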