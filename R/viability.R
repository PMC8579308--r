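#' Dead-cell fraction versus height in the oxic shell
#'
#' Both channels are thresholded (within the colony mask), and the dead
#' fraction in each height bin is the colocalized thresholded volume (both
#' stable reporter and dead stain positive) divided by the thresholded
#' stable-reporter volume. Only voxels within \code{shellDepth} um of the
#' air-facing surface are considered (the oxic shell, where the
#' oxygen-dependent stable reporter is reliable); binning is by height z
#' above the base plane - two different coordinates, both required.
#'
#' @param image a \linkS4class{VoxelImage} containing both channels.
#' @param mask a \linkS4class{ColonyMask}.
#' @param distmap a \linkS4class{SurfaceDistanceMap}.
#' @param stableChannel,deadChannel channel names.
#' @param shellDepth oxic shell depth (um), default 30.
#' @param heightBin height bin width (um).
#' @param stableThreshold,deadThreshold "otsu" (within the mask) or fixed
#'   values.
#' @return data.frame: height_um (bin centers), dead_fraction (NA where no
#'   stable-positive voxels), n_stable, n_voxels. Attributes carry the
#'   thresholds used.
#' @export
deadFractionProfile <- function(image, mask, distmap,
                                stableChannel = "stable",
                                deadChannel = "dead",
                                shellDepth = 30, heightBin = 10,
                                stableThreshold = "otsu",
                                deadThreshold = "otsu") {
    stopifnot(shellDepth > 0, heightBin > 0)
    s <- getChannel(image, stableChannel)
    dd <- getChannel(image, deadChannel)
    m <- maskArray(mask)
    dmap <- distanceArray(distmap)
    vs <- voxelSize(mask)
    thrS <- .resolveThreshold(s[m], stableThreshold)
    thrD <- .resolveThreshold(dd[m], deadThreshold)
    shell <- m & !is.na(dmap) & dmap <= shellDepth
    if (!any(shell)) stop("oxic shell is empty")
    d3 <- dim(m)
    zArr <- array(rep((seq_len(d3[3]) - 0.5) * vs[3], each = d3[1] * d3[2]),
                  d3)
    zv <- zArr[shell]
    sPos <- s[shell] > thrS
    dPos <- dd[shell] > thrD
    if (!any(sPos)) stop("stable channel empty after thresholding")
    bin <- floor(zv / heightBin)
    ub <- sort(unique(bin))
    f <- factor(bin, levels = ub)
    nTot <- as.numeric(table(f))
    nS <- as.numeric(rowsum(as.numeric(sPos), bin))
    nBoth <- as.numeric(rowsum(as.numeric(sPos & dPos), bin))
    frac <- ifelse(nS > 0, nBoth / nS, NA_real_)
    out <- data.frame(height_um = (ub + 0.5) * heightBin,
                      dead_fraction = frac, n_stable = nS, n_voxels = nTot)
    attr(out, "thresholds") <- c(stable = thrS, dead = thrD)
    attr(out, "shellDepth_um") <- shellDepth
    out
}

#' Ratiometric growth readout: unstable/stable fold-change between heights
#'
#' The unstable-to-stable reporter ratio is a growth-rate readout (the
#' degradation-tagged protein is diluted more slowly in slow-growing cells).
#' Per height bin in the oxic shell, the ratio is the quotient of the bin
#' sums (not the mean of per-voxel quotients, which is unstable at dim
#' voxels); the fold-change is the ratio in a bin centered at \code{hHi}
#' divided by the ratio in a bin centered at \code{hLo} (clipped at the base
#' plane). Per-channel backgrounds (median outside the mask) are subtracted
#' first by default.
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param mask a \linkS4class{ColonyMask}.
#' @param distmap a \linkS4class{SurfaceDistanceMap}.
#' @param unstableChannel,stableChannel channel names.
#' @param hHi,hLo comparison heights (um), defaults 100 and 0.
#' @param shellDepth oxic shell depth (um), default 30.
#' @param binWidth height bin width (um) for the query bins and the ratio
#'   table.
#' @param backgroundSubtract subtract per-channel background first.
#' @return list: fold_change, ratio_hi, ratio_lo, table (data.frame
#'   height_um, ratio, n_voxels over aligned bins), backgrounds.
#' @export
reporterRatioFoldChange <- function(image, mask, distmap,
                                    unstableChannel = "unstable",
                                    stableChannel = "stable",
                                    hHi = 100, hLo = 0, shellDepth = 30,
                                    binWidth = 5,
                                    backgroundSubtract = TRUE) {
    m <- maskArray(mask)
    vs <- voxelSize(mask)
    bg <- c(unstable = 0, stable = 0)
    if (backgroundSubtract) {
        image <- subtractBackground(image, mask,
                                    c(unstableChannel, stableChannel))
        bg <- attr(image, "backgrounds")
    }
    u <- getChannel(image, unstableChannel)
    s <- getChannel(image, stableChannel)
    dmap <- distanceArray(distmap)
    d3 <- dim(m)
    colonyTop <- max(which(apply(m, 3, any))) * vs[3]
    if (hHi > colonyTop)
        stop("query height ", hHi, " um exceeds the colony height (",
             colonyTop, " um)")
    shell <- m & !is.na(dmap) & dmap <= shellDepth
    zArr <- array(rep((seq_len(d3[3]) - 0.5) * vs[3], each = d3[1] * d3[2]),
                  d3)
    zv <- zArr[shell]
    uv <- u[shell]; sv <- s[shell]

    ratioAt <- function(h) {
        selz <- zv >= max(h - binWidth / 2, 0) & zv < h + binWidth / 2
        if (!any(selz))
            stop("no oxic-shell voxels in the bin at height ", h, " um")
        ssum <- sum(sv[selz])
        if (ssum <= 0)
            stop("zero stable signal in the bin at height ", h, " um")
        sum(uv[selz]) / ssum
    }
    rHi <- ratioAt(hHi)
    rLo <- ratioAt(hLo)

    bin <- floor(zv / binWidth)
    ub <- sort(unique(bin))
    uSum <- as.numeric(rowsum(uv, bin))
    sSum <- as.numeric(rowsum(sv, bin))
    cnt <- as.numeric(table(factor(bin, levels = ub)))
    tab <- data.frame(height_um = (ub + 0.5) * binWidth,
                      ratio = ifelse(sSum > 0, uSum / sSum, NA_real_),
                      n_voxels = cnt)
    list(fold_change = rHi / rLo, ratio_hi = rHi, ratio_lo = rLo,
         table = tab, backgrounds = bg)
}

#' Strain ratio in a ring around the inoculation spot
#'
#' Measures each strain's thresholded area within a ring of width
#' \code{ringWidth} at distance \code{ringDistance} from the edge of the
#' inoculation spot, and reports the strain-1 fraction
#' area1 / (area1 + area2).
#'
#' @param ch1,ch2 2D intensity matrices (one per strain reporter; use
#'   max-projections for 3D acquisitions).
#' @param inoculumMask logical 2D mask of the inoculation spot.
#' @param pixelSize pixel edge length (um); square pixels assumed.
#' @param ringDistance distance from the inoculum edge to the inner ring
#'   radius (um), default 350.
#' @param ringWidth ring width (um), default 35.
#' @param threshold "otsu" (within the ring, per channel) or a fixed value.
#' @return list: fraction1, fraction2 (= 1 - fraction1), area1_um2,
#'   area2_um2, n_ring_pixels, ringDistance_um, ringWidth_um.
#' @export
competitionRingRatio <- function(ch1, ch2, inoculumMask, pixelSize = 1,
                                 ringDistance = 350, ringWidth = 35,
                                 threshold = "otsu") {
    stopifnot(identical(dim(ch1), dim(ch2)),
              identical(dim(ch1), dim(inoculumMask)))
    if (!any(inoculumMask)) stop("empty inoculum mask")
    outside <- !inoculumMask
    dpx <- EBImage::distmap(matrix(as.integer(outside), nrow(outside),
                                   ncol(outside)))
    dum <- (as.numeric(dpx) - 0.5) * pixelSize
    ring <- outside & dum >= ringDistance & dum < ringDistance + ringWidth
    if (!any(ring)) stop("ring is empty; image too small for ringDistance")
    v1 <- ch1[ring]; v2 <- ch2[ring]
    thr1 <- .resolveThreshold(v1, threshold)
    thr2 <- .resolveThreshold(v2, threshold)
    pxArea <- pixelSize^2
    a1 <- sum(v1 > thr1) * pxArea
    a2 <- sum(v2 > thr2) * pxArea
    if (a1 + a2 == 0) stop("no thresholded signal in the ring")
    list(fraction1 = a1 / (a1 + a2), fraction2 = a2 / (a1 + a2),
         area1_um2 = a1, area2_um2 = a2, n_ring_pixels = sum(ring),
         ringDistance_um = ringDistance, ringWidth_um = ringWidth)
}

#' Normalize a bulk signal by a volume, density or count denominator
#'
#' Bulk measurements are made comparable across samples by dividing by the
#' appropriate size proxy: total biovolume (um^3) for whole-colony
#' measurements, colony number times mean colony volume for per-colony
#' extracellular measurements, or optical density for liquid cultures.
#'
#' @param signal measured signal (a.u.).
#' @param denom positive denominator in the units of \code{mode}.
#' @param mode which normalization is applied: "biovolume",
#'   "count_x_volume", or "od600".
#' @return list: value (signal/denom), mode, denom.
#' @export
normalizeSignal <- function(signal,
                            denom,
                            mode = c("biovolume", "count_x_volume",
                                     "od600")) {
    mode <- match.arg(mode)
    if (!is.finite(denom) || denom <= 0)
        stop("denominator must be positive")
    list(value = signal / denom, mode = mode, denom = denom)
}
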