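#' Euclidean distance to the air-facing colony surface
#'
#' The surface set is every mask voxel with a 6-connected neighbor that is
#' air: outside the mask or beyond the grid, except below the base plane,
#' which is substrate (the colony sits on a filter membrane, and oxygen
#' arrives from the air side). Distances are exact Euclidean distances
#' between voxel centers, computed with a separable parabolic-envelope
#' distance transform using the physical per-axis voxel spacing, so
#' anisotropic stacks are handled correctly.
#'
#' @param mask a \linkS4class{ColonyMask} (nonempty).
#' @param includeBase if TRUE, substrate contact also counts as exposed
#'   surface (distance-to-any-boundary rather than air-facing).
#' @return a \linkS4class{SurfaceDistanceMap}; NA outside the mask, 0 on
#'   surface voxels.
#' @export
surfaceDistanceMap <- function(mask, includeBase = FALSE) {
    m <- maskArray(mask)
    if (!any(m)) stop("empty mask")
    d <- dim(m)
    air <- array(FALSE, d)
    # +x / -x / +y / -y neighbors (out of grid counts as air)
    sh <- function(arr, ax, by) {
        out <- array(TRUE, d)  # beyond the grid: air
        if (ax == 1) {
            if (by == 1) out[1:(d[1] - 1), , ] <- !arr[2:d[1], , ]
            else out[2:d[1], , ] <- !arr[1:(d[1] - 1), , ]
        } else if (ax == 2) {
            if (by == 1) out[, 1:(d[2] - 1), ] <- !arr[, 2:d[2], ]
            else out[, 2:d[2], ] <- !arr[, 1:(d[2] - 1), ]
        } else {
            if (by == 1) out[, , 1:(d[3] - 1)] <- !arr[, , 2:d[3]]
            else out[, , 2:d[3]] <- !arr[, , 1:(d[3] - 1)]
        }
        out
    }
    air <- sh(m, 1, 1) | sh(m, 1, -1) | sh(m, 2, 1) | sh(m, 2, -1) |
        sh(m, 3, 1)
    below <- sh(m, 3, -1)
    if (includeBase) {
        air <- air | below
    } else {
        # below the lowest grid plane lies the substrate, not air
        below[, , 1] <- FALSE
        air <- air | below
    }
    surface <- m & air
    if (!any(surface))
        stop("mask has no air-facing surface voxels")
    dist <- .edt3d_cpp(as.logical(surface), as.integer(d),
                       as.numeric(voxelSize(mask)))
    dim(dist) <- d
    dist[!m] <- NA_real_
    new("SurfaceDistanceMap", distance = dist,
        voxelSize = voxelSize(mask), includeBase = includeBase)
}

# Otsu threshold of a value vector (rescaled into [0,1] for EBImage::otsu,
# then mapped back to the original intensity scale).
.otsuWithin <- function(vals) {
    lo <- min(vals); hi <- max(vals)
    if (hi <= lo) return(lo)
    v01 <- matrix((vals - lo) / (hi - lo), nrow = 1)
    EBImage::otsu(v01) * (hi - lo) + lo
}

.resolveThreshold <- function(vals, threshold) {
    if (identical(threshold, "otsu")) .otsuWithin(vals)
    else if (is.numeric(threshold) && length(threshold) == 1) threshold
    else stop("threshold must be 'otsu' or a single numeric value")
}

#' Intensity profile over distance-to-surface shells
#'
#' Groups all colony voxels by their distance to the air-facing surface
#' (isotropic shells of width \code{binWidth}) and averages the intensity in
#' each shell; locations with a similar distance to the surface are averaged
#' irrespective of the orientation of the measurement axis. The normalized
#' column divides by the mean over the outermost \code{surfaceRef} um
#' (surface reference shell), so it is 1 at the surface.
#'
#' @param image a \linkS4class{VoxelImage} or a 3D intensity array.
#' @param distmap a \linkS4class{SurfaceDistanceMap}.
#' @param binWidth shell width (um), > 0.
#' @param channel channel name when \code{image} is a VoxelImage.
#' @param surfaceRef width (um) of the surface shell used as the
#'   normalization reference.
#' @return data.frame: distance_um (bin centers), mean_intensity, n_voxels,
#'   normalized. Empty bins are omitted.
#' @export
shellProfile <- function(image, distmap, binWidth = 2, channel = NULL,
                         surfaceRef = 2) {
    stopifnot(binWidth > 0)
    arr <- if (is(image, "VoxelImage"))
        getChannel(image, .defaultChannel(image, channel)) else image
    d <- distanceArray(distmap)
    stopifnot(identical(dim(arr), dim(d)))
    sel <- !is.na(d)
    dv <- d[sel]; iv <- arr[sel]
    bin <- floor(dv / binWidth)
    ub <- sort(unique(bin))
    sums <- as.numeric(rowsum(iv, bin))
    cnt <- as.numeric(table(factor(bin, levels = ub)))
    means <- sums / cnt
    ref <- mean(iv[dv <= surfaceRef])
    data.frame(distance_um = (ub + 0.5) * binWidth,
               mean_intensity = means, n_voxels = cnt,
               normalized = means / ref)
}

#' Axial-cylinder fluorescence profile
#'
#' Mean intensity per z-slice within a vertical cylinder of radius
#' \code{cylRadius} centered on the colony axis (the basal-footprint
#' centroid), normalized to the fluorescence at the colony surface: the mean
#' over the topmost \code{refDepth} um of the cylinder.
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param mask a \linkS4class{ColonyMask}.
#' @param channel channel name (default "stable" when present).
#' @param cylRadius cylinder radius in um (default 3.3).
#' @param refDepth depth (um) below the cylinder top used as the surface
#'   normalization reference.
#' @return data.frame: z_um (slice center heights), mean_intensity,
#'   n_voxels, normalized; only slices with colony voxels in the cylinder.
#' @export
axialCylinderProfile <- function(image, mask, channel = NULL,
                                 cylRadius = 3.3, refDepth = 2) {
    channel <- .defaultChannel(image, channel)
    arr <- getChannel(image, channel)
    m <- maskArray(mask)
    vs <- voxelSize(mask)
    d <- dim(m)
    k0 <- which(apply(m, 3, any))[1]
    idx <- which(m[, , k0], arr.ind = TRUE)
    cx <- (mean(idx[, 1]) - 0.5) * vs[1]
    cy <- (mean(idx[, 2]) - 0.5) * vs[2]
    xs <- (seq_len(d[1]) - 0.5) * vs[1]
    ys <- (seq_len(d[2]) - 0.5) * vs[2]
    incyl <- outer((xs - cx)^2, (ys - cy)^2, "+") <= cylRadius^2
    if (!any(incyl)) stop("cylinder contains no voxels")
    zc <- (seq_len(d[3]) - 0.5) * vs[3]
    means <- numeric(d[3]); cnt <- integer(d[3])
    for (k in seq_len(d[3])) {
        s <- incyl & m[, , k]
        cnt[k] <- sum(s)
        means[k] <- if (cnt[k] > 0) mean(arr[, , k][s]) else NA_real_
    }
    if (all(cnt == 0)) stop("cylinder contains no colony voxels")
    keep <- cnt > 0
    topZ <- max(zc[keep])
    refSel <- keep & zc > topZ - refDepth
    ref <- sum(means[refSel] * cnt[refSel]) / sum(cnt[refSel])
    data.frame(z_um = zc[keep], mean_intensity = means[keep],
               n_voxels = cnt[keep], normalized = means[keep] / ref)
}

#' Basal-plane fluorescence profile
#'
#' Intensity in the horizontal plane at the colony base versus the in-plane
#' distance to the colony edge (2D Euclidean distance transform of the base
#' footprint), normalized to the colony-air interface within the same plane
#' (the first populated distance bin).
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param mask a \linkS4class{ColonyMask}.
#' @param channel channel name (default "stable" when present).
#' @param baseZ base slice index; default the lowest occupied slice.
#' @param binWidth distance bin width (um).
#' @return data.frame: distance_um (in-plane distance to the edge, bin
#'   centers), mean_intensity, n_voxels, normalized.
#' @export
basalPlaneProfile <- function(image, mask, channel = NULL, baseZ = NULL,
                              binWidth = 2) {
    channel <- .defaultChannel(image, channel)
    arr <- getChannel(image, channel)
    m <- maskArray(mask)
    vs <- voxelSize(mask)
    if (abs(vs[1] - vs[2]) > 1e-6 * vs[1])
        stop("basal profile requires square xy pixels")
    if (is.null(baseZ)) baseZ <- which(apply(m, 3, any))[1]
    foot <- m[, , baseZ]
    if (!any(foot)) stop("base slice is empty")
    dpx <- EBImage::distmap(matrix(as.integer(foot), nrow(foot), ncol(foot)))
    dum <- (as.numeric(dpx[foot]) - 0.5) * vs[1]
    iv <- arr[, , baseZ][foot]
    bin <- floor(dum / binWidth)
    ub <- sort(unique(bin))
    sums <- as.numeric(rowsum(iv, bin))
    cnt <- as.numeric(table(factor(bin, levels = ub)))
    means <- sums / cnt
    data.frame(distance_um = (ub + 0.5) * binWidth,
               mean_intensity = means, n_voxels = cnt,
               normalized = means / means[1])
}

#' Fluorescent volume fraction of a colony
#'
#' Number of colony voxels with intensity above the threshold, divided by
#' the total number of colony voxels (fluorescent volume over total volume).
#'
#' @param image a \linkS4class{VoxelImage} or 3D array.
#' @param mask a \linkS4class{ColonyMask} (nonempty).
#' @param threshold "otsu" (computed within the mask) or a fixed value >= 0.
#' @param channel channel name when \code{image} is a VoxelImage.
#' @return fraction in [0, 1], with attribute \code{threshold}.
#' @export
fluorescentFraction <- function(image, mask, threshold = "otsu",
                                channel = NULL) {
    arr <- if (is(image, "VoxelImage"))
        getChannel(image, .defaultChannel(image, channel)) else image
    m <- maskArray(mask)
    if (!any(m)) stop("empty mask")
    vals <- arr[m]
    thr <- .resolveThreshold(vals, threshold)
    f <- mean(vals > thr)
    attr(f, "threshold") <- thr
    f
}

#' Estimate a fluorescence decay length from a shell profile
#'
#' Least-squares line fit of log(mean intensity) versus distance over
#' populated bins; the decay length is -1/slope. Bins below \code{minCount}
#' voxels or below \code{relFloor} times the peak bin mean (the profile's
#' usable dynamic range; deeper bins sit at the noise floor) are excluded.
#'
#' @param profile a data.frame from \code{\link{shellProfile}} (columns
#'   distance_um, mean_intensity, n_voxels) or any profile with those
#'   columns.
#' @param minCount minimum voxels per bin.
#' @param relFloor relative intensity floor for bin inclusion.
#' @return list: lambda_um, slope (1/um), r_squared, n_bins.
#' @export
fitDecayLength <- function(profile, minCount = 50, relFloor = 0.05) {
    ok <- profile$n_voxels >= minCount & profile$mean_intensity > 0
    prof <- profile[ok, , drop = FALSE]
    if (nrow(prof) > 0)
        prof <- prof[prof$mean_intensity >=
                     relFloor * max(prof$mean_intensity), , drop = FALSE]
    if (nrow(prof) < 4)
        stop("fewer than 4 usable bins for the decay fit")
    fit <- stats::lm(log(mean_intensity) ~ distance_um, data = prof)
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= -1e-12)
        stop("profile does not decay; decay length undefined")
    y <- log(prof$mean_intensity)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    list(lambda_um = -1 / slope, slope = slope,
         r_squared = r2, n_bins = nrow(prof))
}

#' Subtract a per-channel background estimated outside the colony
#'
#' The background of each channel is the median intensity over voxels
#' outside the colony mask; it is subtracted from the whole channel.
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param mask a \linkS4class{ColonyMask}.
#' @param channels channels to correct (default all).
#' @return the corrected \linkS4class{VoxelImage}, with attribute
#'   \code{backgrounds} (named numeric).
#' @export
subtractBackground <- function(image, mask, channels = NULL) {
    if (is.null(channels)) channels <- channelNames(image)
    m <- maskArray(mask)
    if (all(m)) stop("mask covers the whole grid; no background region")
    bg <- numeric(0)
    for (ch in channels) {
        arr <- getChannel(image, ch)
        b <- stats::median(arr[!m])
        image@channels[[ch]] <- arr - b
        bg[ch] <- b
    }
    attr(image, "backgrounds") <- bg
    image
}
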