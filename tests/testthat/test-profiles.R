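test_that("surface distance is zero on surface voxels and handles slabs", {
    # single-voxel colony is all surface
    m1 <- array(FALSE, c(5, 5, 3)); m1[3, 3, 1] <- TRUE
    d1 <- surfaceDistanceMap(ColonyMask(m1, c(1, 1, 1)))
    expect_equal(distanceArray(d1)[3, 3, 1], 0)
    # slab of thickness 20 um on the substrate: distance = depth below the
    # top voxel layer (checked away from the lateral edges, which must be
    # farther than the depth for the half-space closed form to apply)
    m <- array(TRUE, c(60, 60, 20))
    dm <- surfaceDistanceMap(ColonyMask(m, c(1, 1, 1)))
    da <- distanceArray(dm)
    for (k in c(1, 5, 10, 20))
        expect_true(all(da[25:36, 25:36, k] == 20 - k))
    # with the base counted as surface the bottom also reads 0
    dmb <- surfaceDistanceMap(ColonyMask(m, c(1, 1, 1)), includeBase = TRUE)
    dab <- distanceArray(dmb)
    for (k in c(1, 5, 10, 20))
        expect_true(all(dab[25:36, 25:36, k] == pmin(20 - k, k - 1)))
    expect_error(surfaceDistanceMap(
        ColonyMask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))), "empty")
})

test_that("distance transform equals the brute-force oracle exactly", {
    for (seed in 1:3) {
        m <- randomBlobMask(seed)
        vs <- if (seed == 3) c(0.5, 0.5, 2) else c(1, 1, 1)
        dm <- surfaceDistanceMap(ColonyMask(m, vs))
        bf <- bruteSurfaceDistance(m, vs)
        expect_lt(max(abs(distanceArray(dm) - bf), na.rm = TRUE), 1e-9)
    }
    # includeBase variant agrees with its oracle too
    m <- randomBlobMask(11)
    dm <- surfaceDistanceMap(ColonyMask(m, c(1, 1, 1)), includeBase = TRUE)
    bf <- bruteSurfaceDistance(m, c(1, 1, 1), includeBase = TRUE)
    expect_lt(max(abs(distanceArray(dm) - bf), na.rm = TRUE), 1e-9)
})

test_that("shell profile averages by distance and normalizes at the surface", {
    rc <- smallColony()
    m <- maskArray(rc$truth@mask)
    # uniform colony: every bin mean equal, normalized identically 1
    uni <- array(0, dim(m)); uni[m] <- 42
    shp <- shellProfile(uni, rc$truth@distance, binWidth = 2)
    expect_true(all(shp$mean_intensity == 42))
    expect_true(all(shp$normalized == 1))
    expect_equal(sum(shp$n_voxels), sum(m))
    # exponential field: bin means within 3% of exp(-d_center/20)
    shp2 <- shellProfile(rc$truth@noiseless$stable, rc$truth@distance,
                         binWidth = 2)
    expctd <- 200 * exp(-shp2$distance_um / 20)
    expect_lt(max(abs(shp2$mean_intensity / expctd - 1)), 0.03)
    # monotone field gives monotone bin means
    expect_true(all(diff(shp2$mean_intensity) < 0))
    # no bins beyond the attained distance range
    expect_lte(max(shp2$distance_um),
               max(distanceArray(rc$truth@distance), na.rm = TRUE) + 1)
})

test_that("axial cylinder profile is normalized at the apex surface", {
    rc <- smallColony()
    m <- maskArray(rc$truth@mask)
    uni <- array(0, dim(m)); uni[m] <- 7
    img <- VoxelImage(list(stable = uni), voxelSize(rc$image))
    axp <- axialCylinderProfile(img, rc$truth@mask)
    expect_true(all(abs(axp$normalized - 1) < 1e-12))
    # default cylinder radius is 3.3 um
    expect_equal(formals(axialCylinderProfile)$cylRadius, 3.3)
    # exponential field: fitted decay length close to the generator lambda
    tall <- tallColony()
    fit <- axialLambda(axialCylinderProfile(tall$image, tall$truth@mask))
    expect_lt(abs(fit$lambda_um - 20) / 20, 0.05)
})

test_that("basal plane profile decays with in-plane edge distance", {
    rc <- smallColony()
    m <- maskArray(rc$truth@mask)
    uni <- array(0, dim(m)); uni[m] <- 3
    img <- VoxelImage(list(stable = uni), voxelSize(rc$image))
    bp <- basalPlaneProfile(img, rc$truth@mask)
    expect_true(all(bp$normalized == 1))
    # the generator's in-plane decay near the rim approximates the 3D decay
    bp2 <- basalPlaneProfile(rc$image, rc$truth@mask)
    fit <- fitDecayLength(bp2[bp2$distance_um <= 20, ], minCount = 50,
                          relFloor = 0)
    expect_lt(abs(fit$lambda_um - 20) / 20, 0.15)
    # single-pixel-wide footprint: a single bin of value 1
    m1 <- array(FALSE, c(9, 9, 2)); m1[5, 5, 1] <- TRUE
    img1 <- VoxelImage(list(stable = array(10, c(9, 9, 2))), c(1, 1, 1))
    bp1 <- basalPlaneProfile(img1, ColonyMask(m1, c(1, 1, 1)))
    expect_equal(nrow(bp1), 1)
    expect_equal(bp1$normalized, 1)
})

test_that("fluorescent fraction counts thresholded colony volume", {
    rc <- smallColony()
    tr <- rc$truth
    m <- maskArray(tr@mask)
    stable <- tr@noiseless$stable
    expect_equal(as.numeric(
        fluorescentFraction(stable, tr@mask, threshold = 1e9)), 0)
    expect_equal(as.numeric(
        fluorescentFraction(stable, tr@mask, threshold = 0)), 1)
    # threshold at half the surface intensity selects d < lambda ln 2
    f <- fluorescentFraction(stable, tr@mask, threshold = 100)
    truthFrac <- mean(distanceArray(tr@distance)[m] < 20 * log(2))
    expect_lt(abs(as.numeric(f) - truthFrac), 0.03)
    # non-increasing in the threshold
    fr <- vapply(c(0, 10, 50, 100, 150), function(th) as.numeric(
        fluorescentFraction(stable, tr@mask, threshold = th)), numeric(1))
    expect_true(all(diff(fr) <= 0))
    expect_error(fluorescentFraction(stable,
        ColonyMask(array(FALSE, dim(m)), c(1, 1, 1))), "empty")
})

test_that("decay-length fit is exact on exact data and rejects flat input", {
    d <- seq(1, 41, by = 2)
    prof <- data.frame(distance_um = d,
                       mean_intensity = 100 * exp(-d / 20),
                       n_voxels = rep(1000L, length(d)))
    fit <- fitDecayLength(prof)
    expect_equal(fit$lambda_um, 20, tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-10)
    flat <- data.frame(distance_um = d, mean_intensity = rep(5, length(d)),
                       n_voxels = rep(1000L, length(d)))
    expect_error(fitDecayLength(flat), "does not decay")
    expect_error(fitDecayLength(prof[1:3, ]), "fewer than 4")
})

test_that("axial, basal and shell geometries recover one decay length", {
    rc <- smallColonyNoisy()
    corr <- subtractBackground(rc$image, rc$truth@mask, "stable")
    lamShell <- fitDecayLength(
        shellProfile(corr, rc$distmap, channel = "stable"))$lambda_um
    lamAx <- axialLambda(
        axialCylinderProfile(corr, rc$truth@mask))$lambda_um
    bp <- basalPlaneProfile(corr, rc$truth@mask)
    lamBas <- fitDecayLength(bp[bp$distance_um <= 20, ], minCount = 50,
                             relFloor = 0)$lambda_um
    for (lam in c(lamShell, lamAx, lamBas))
        expect_lt(abs(lam - 20) / 20, 0.15)
})
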