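#' Height-versus-radius profile of a colony
#'
#' For each radial bin (width = one xy-voxel) around the colony axis, the
#' azimuthal mean of the local colony height: each xy-column contributes the
#' top face of its topmost occupied voxel (0 if the column is empty, so the
#' profile decays to zero at the colony edge). No monotone cleanup is
#' applied, preserving mid-height bulges. The axis is the centroid of the
#' basal footprint (lowest occupied slice).
#'
#' @param mask a \linkS4class{ColonyMask} (nonempty).
#' @return data.frame (r_um, height_um) with attributes \code{center}
#'   (x, y in um) and \code{voxelSize}.
#' @export
heightRadiusProfile <- function(mask) {
    m <- maskArray(mask)
    if (!any(m)) stop("empty mask")
    vs <- voxelSize(mask)
    dx <- vs[1]; dy <- vs[2]; dz <- vs[3]
    d <- dim(m)
    # topmost occupied slice index per column (0 when empty)
    top <- matrix(0L, d[1], d[2])
    for (k in seq_len(d[3])) {
        mk <- m[, , k]
        top[mk] <- k
    }
    occ <- top > 0L
    k0 <- which(apply(m, 3, any))[1]
    foot <- m[, , k0]
    idx <- which(foot, arr.ind = TRUE)
    cx <- (mean(idx[, 1]) - 0.5) * dx
    cy <- (mean(idx[, 2]) - 0.5) * dy
    xs <- (seq_len(d[1]) - 0.5) * dx
    ys <- (seq_len(d[2]) - 0.5) * dy
    r2d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
    h2d <- top * dz
    bin <- floor(r2d / dx)
    binMaxOcc <- max(bin[occ])
    sel <- bin <= binMaxOcc + 1
    bv <- bin[sel]
    hv <- h2d[sel]
    ub <- sort(unique(bv))
    hMean <- as.numeric(rowsum(hv, bv)) /
        as.numeric(table(factor(bv, levels = ub)))
    prof <- data.frame(r_um = (ub + 0.5) * dx, height_um = hMean)
    attr(prof, "center") <- c(x_um = cx, y_um = cy)
    attr(prof, "voxelSize") <- vs
    prof
}

# centered moving average with shrinking windows at the edges
.movavg <- function(x, window) {
    h <- window %/% 2
    n <- length(x)
    vapply(seq_len(n),
        function(i) mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Slope of the height-radius profile at a query height
#'
#' Locates the radius r* where the (smoothed) profile attains
#' \code{hQuery} by linear interpolation, and evaluates dh/dr there by
#' central finite differences of the smoothed profile. Negative for
#' outward-decreasing domes; a less negative slope at mid-height indicates
#' the convex "bulge" morphology, a more negative one a conical shape.
#'
#' @param profile a height-radius profile from
#'   \code{\link{heightRadiusProfile}}.
#' @param hQuery query height (um); must lie within the profile's range.
#' @param window moving-average smoothing window (radial bins) applied
#'   before differencing.
#' @return dimensionless slope dh/dr, with attributes \code{r_star_um}.
#' @export
slopeAtHeight <- function(profile, hQuery, window = 5) {
    r <- profile$r_um
    h <- profile$height_um
    if (length(r) < max(3, window))
        stop("profile too short")
    hs <- .movavg(h, window)
    if (hQuery > max(hs) || hQuery < min(hs))
        stop("height ", hQuery, " um not attained by the profile (range ",
             signif(min(hs), 4), " - ", signif(max(hs), 4), " um)")
    cross <- which((hs[-length(hs)] - hQuery) * (hs[-1] - hQuery) <= 0)
    if (length(cross) == 0)
        stop("height ", hQuery, " um not attained by the profile")
    i <- cross[1]
    f <- if (hs[i + 1] == hs[i]) 0 else (hQuery - hs[i]) / (hs[i + 1] - hs[i])
    rStar <- r[i] + f * (r[i + 1] - r[i])
    n <- length(r)
    deriv <- rep(NA_real_, n)
    deriv[2:(n - 1)] <- (hs[3:n] - hs[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
    deriv[1] <- deriv[2]; deriv[n] <- deriv[n - 1]
    slope <- stats::approx(r, deriv, xout = rStar, rule = 2)$y
    attr(slope, "r_star_um") <- rStar
    slope
}

#' Scalar morphometrics of a colony mask
#'
#' @param mask a \linkS4class{ColonyMask}.
#' @param hQuery height (um) at which the bulge metric (slope of the
#'   height-radius profile) is evaluated; NA if not attained.
#' @param window smoothing window for \code{\link{slopeAtHeight}}.
#' @return list: height_um (apex), radius_um (largest radius with nonzero
#'   profile height), slope_at_height, hQuery_um, profile.
#' @export
morphologyMetrics <- function(mask, hQuery = 100, window = 5) {
    prof <- heightRadiusProfile(mask)
    height <- max(prof$height_um)
    nzr <- prof$r_um[prof$height_um > 0]
    radius <- if (length(nzr)) max(nzr) else 0
    slope <- tryCatch(slopeAtHeight(prof, hQuery, window = window),
                      error = function(e) NA_real_)
    list(height_um = height, radius_um = radius,
         slope_at_height = as.numeric(slope), hQuery_um = hQuery,
         profile = prof)
}
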