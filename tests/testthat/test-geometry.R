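mkdisk <- function(n, cx, cy, r, val = 100) {
    rr <- sqrt(outer((1:n - cx)^2, (1:n - cy)^2, "+"))
    ifelse(rr <= r, val, 0)
}

test_that("gradient segmentation recovers sharp-edged shapes", {
    # constant slice: zero gradient, empty mask
    expect_equal(sum(segmentSlice(matrix(7, 32, 32))), 0)
    # noiseless disk, radius 20 um at 1 um/px: area within 5%
    m <- segmentSlice(mkdisk(60, 30, 30, 20))
    expect_lt(abs(convexArea(m) - pi * 400) / (pi * 400), 0.05)
    # largest-component rule: of two disks only the bigger survives
    two <- mkdisk(60, 15, 15, 6) + mkdisk(60, 40, 40, 12)
    m2 <- segmentSlice(two)
    lab <- EBImage::bwlabel(matrix(as.integer(m2), 60, 60))
    expect_equal(max(lab), 1)
    idx <- which(m2, arr.ind = TRUE)
    expect_true(all(sqrt((idx[, 1] - 40)^2 + (idx[, 2] - 40)^2) < 14))
})

test_that("convex area matches hull geometry and dominates raw area", {
    expect_equal(convexArea(matrix(FALSE, 10, 10)), 0)
    # a filled square is its own hull
    sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
    expect_equal(convexArea(sq, c(1, 1)), 100)
    expect_equal(convexArea(sq, c(0.5, 0.5)), 25)
    # C-shaped sector: hull area >= raw area, and equals hull of its hull
    n <- 50; rr <- sqrt(outer((1:n - 25)^2, (1:n - 25)^2, "+"))
    ang <- atan2(outer(rep(1, n), 1:n - 25), outer(1:n - 25, rep(1, n)))
    cshape <- rr <= 20 & rr >= 12 & abs(ang) > pi / 4
    expect_gte(convexArea(cshape), sum(cshape))
    # fixed point: rasterized hull of the C has the same convex area
    hullpix <- matrix(FALSE, n, n)
    idx <- which(cshape, arr.ind = TRUE)
    h <- grDevices::chull(idx)
    inside <- colonyvox:::.points_in_polygon_cpp(
        as.numeric(rep(1:n, times = n)), as.numeric(rep(1:n, each = n)),
        as.numeric(idx[h, 1]), as.numeric(idx[h, 2]))
    hullpix[cbind(rep(1:n, times = n)[inside],
                  rep(1:n, each = n)[inside])] <- TRUE
    expect_equal(convexArea(hullpix), convexArea(cshape))
    # degenerate line of pixels falls back to the pixel count
    ln <- matrix(FALSE, 10, 10); ln[3, 2:8] <- TRUE
    expect_equal(convexArea(ln), 7)
})

test_that("biovolume sums per-slice convex areas times slice spacing", {
    expect_error(
        biovolume(VoxelImage(list(stable = array(0, c(16, 16, 4))),
                             c(1, 1, 1))), "no colony")
    # solid cuboid 10 x 10 x 5 um at 1 um voxels: exactly 500 um^3
    arr <- array(0, c(30, 30, 8)); arr[11:20, 11:20, 1:5] <- 100
    bv <- biovolume(VoxelImage(list(stable = arr), c(1, 1, 1)),
                    minSliceArea = 5)
    expect_equal(bv$biovolume_um3, 500)
    expect_equal(bv$perSlice$area_um2, c(rep(100, 5), rep(0, 3)))
})

test_that("overview detection finds colonies at their true centers", {
    expect_equal(nrow(detectColonies(matrix(0, 50, 50))), 0)
    ov <- renderOverview(5, colonySpec(R = 50, H = 50, seed = 4L))
    det <- detectColonies(ov$image, ov$pixelSize, minArea = 1000)
    expect_equal(nrow(det), 5)
    tru <- ov$centers[order(ov$centers$x_um), ]
    est <- det[order(det$x_um), ]
    expect_true(all(abs(est$x_um - tru$x_um) <= 1))
    expect_true(all(abs(est$y_um - tru$y_um) <= 1))
    expect_true(all(abs(est$area_um2 - pi * 50^2) / (pi * 50^2) < 0.05))
    # touching disks merge into a single component
    touching <- mkdisk(60, 20, 30, 10) + mkdisk(60, 38, 30, 10)
    expect_equal(nrow(detectColonies(pmin(touching, 100), 1,
                                     minArea = 10)), 1)
})

test_that("the substrate plane is located from the beads channel", {
    rc <- smallColony()
    expect_equal(locateFocalPlane(rc$image), 1L)
    # shift beads to slice 3 of a 32-slice stack
    beads <- getChannel(rc$image, "beads")
    shifted <- array(0, c(dim(beads)[1:2], 32))
    shifted[, , 3] <- beads[, , 1]
    img <- VoxelImage(list(beads = shifted), voxelSize(rc$image))
    expect_equal(locateFocalPlane(img), 3L)
    flat <- VoxelImage(list(beads = array(5, c(8, 8, 4))), c(1, 1, 1))
    expect_error(locateFocalPlane(flat), "flat")
})
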