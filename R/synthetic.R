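#' Create a synthetic colony specification
#'
#' Constructor for \linkS4class{SyntheticColonySpec}. Arguments omitted fall
#' back to the package defaults (the study conditions used by the recovery
#' tests); see the class documentation for slot meanings and units.
#'
#' @param shape "power" (default dome family) or "hemisphere".
#' @param H,R apex height and basal radius (um).
#' @param bulgeP shape exponent, >= 1.
#' @param lambdaDecay fluorescence decay length (um).
#' @param surfaceIntensity stable-reporter surface intensity (a.u.).
#' @param deadParams numeric(3) (d0, d1, pmax) of the death-probability ramp.
#' @param ratioParams numeric(2) (g0, g1) of the unstable/stable ratio.
#' @param mixFraction strain-1 fraction for competition rendering.
#' @param noise list(poisson_on, read_sigma, background).
#' @param voxelSize numeric(3) (um).
#' @param margin grid clearance around the dome (um), at least 5.
#' @param nBeads,beadIntensity substrate bead count and intensity.
#' @param seed integer seed for all stochastic draws.
#' @return a validated \linkS4class{SyntheticColonySpec}.
#' @examples
#' spec <- colonySpec(H = 100, R = 100, seed = 7L)
#' shapeHeight(50, spec)
#' @export
colonySpec <- function(shape = "power", H = 150, R = 150, bulgeP = 2,
                       lambdaDecay = 20, surfaceIntensity = 200,
                       deadParams = c(d0 = 50, d1 = 150, pmax = 0.3),
                       ratioParams = c(g0 = 0.3, g1 = 0.01),
                       mixFraction = 0.5,
                       noise = list(poisson_on = TRUE, read_sigma = 2,
                                    background = 5),
                       voxelSize = c(1, 1, 1), margin = 5,
                       nBeads = 12, beadIntensity = 2000, seed = 1L) {
    new("SyntheticColonySpec", shape = shape, H = H, R = R, bulgeP = bulgeP,
        lambdaDecay = lambdaDecay, surfaceIntensity = surfaceIntensity,
        deadParams = deadParams, ratioParams = ratioParams,
        mixFraction = mixFraction, noise = noise,
        voxelSize = as.numeric(voxelSize), margin = margin, nBeads = nBeads,
        beadIntensity = beadIntensity, seed = as.integer(seed))
}

#' Colony height at a radial distance
#'
#' The dome profile of the generated colonies. For the "power" family,
#' \eqn{h(r) = H (1 - (r/R)^p)} for \eqn{r \le R} and 0 beyond: p = 1 gives a
#' cone (no bulge), p = 2 a convex bulged dome. The "hemisphere" shape gives
#' the spherical cap \eqn{h(r) = \sqrt{R^2 - r^2}}, used to validate
#' volumetric and morphometric measurements against closed forms.
#'
#' @param r radial distance(s) from the colony axis (um), >= 0.
#' @param spec a \linkS4class{SyntheticColonySpec}.
#' @return height(s) in um; continuous and non-increasing in r.
#' @export
shapeHeight <- function(r, spec) {
    if (any(r < 0)) stop("r must be non-negative")
    if (spec@H <= 0 || spec@R <= 0) stop("H and R must be positive")
    h <- switch(spec@shape,
        power = spec@H * (1 - (r / spec@R)^spec@bulgeP),
        hemisphere = sqrt(pmax(spec@R^2 - r^2, 0)))
    pmax(h, 0)
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Shot + read noise model: Poisson on (signal + background), then additive
# Gaussian read noise. With poisson_on = FALSE, sigma = 0 and background = 0
# the output equals the input exactly.
.applyNoise <- function(x, noise) {
    lam <- x + noise$background
    if (isTRUE(noise$poisson_on)) {
        d <- dim(lam)
        lam <- as.numeric(stats::rpois(length(lam), lam))
        dim(lam) <- d
    }
    if (noise$read_sigma > 0)
        lam <- lam + stats::rnorm(length(lam), 0, noise$read_sigma)
    lam
}

# Sample the axisymmetric surface curve (rho, h(rho)) approximately uniformly
# in arc length so steep rims (e.g. a hemisphere edge) are not undersampled.
.surfaceCurve <- function(spec, step) {
    rhoF <- seq(0, spec@R, by = step / 20)
    hF <- shapeHeight(rhoF, spec)
    arc <- c(0, cumsum(sqrt(diff(rhoF)^2 + diff(hF)^2)))
    s <- seq(0, arc[length(arc)], by = step)
    cbind(r = stats::approx(arc, rhoF, s, rule = 2)$y,
          h = stats::approx(arc, hF, s, rule = 2)$y)
}

# Exact (to curve-sampling resolution) distance from grid of (r, z) points to
# the continuous air-facing surface, exploiting axisymmetry. Returns a matrix
# length(rGrid) x length(zCenters).
.analyticSurfaceDistance <- function(spec, rGrid, zCenters) {
    step <- min(spec@voxelSize[c(1, 3)]) / 4
    curve <- .surfaceCurve(spec, step)
    dr2 <- outer(rGrid, curve[, "r"], function(a, b) (a - b)^2)
    D <- matrix(NA_real_, length(rGrid), length(zCenters))
    for (k in seq_along(zCenters)) {
        m <- dr2 + matrix((zCenters[k] - curve[, "h"])^2,
                          nrow(dr2), ncol(dr2), byrow = TRUE)
        D[, k] <- sqrt(apply(m, 1, min))
    }
    D
}

#' Render a synthetic colony image with ground truth
#'
#' Rasterizes the dome defined by \code{spec} onto a calibrated voxel grid
#' and renders the reporter channels the analyses consume:
#' \describe{
#'   \item{stable}{constitutive reporter, noiseless intensity
#'     \code{surfaceIntensity * exp(-d / lambdaDecay)} with d the analytic
#'     distance to the air-facing surface (oxygen-maturation proxy).}
#'   \item{dead}{dead-cell stain: equals the stable-reporter intensity at
#'     voxels drawn dead with probability
#'     \code{pmax * clamp((z - d0)/(d1 - d0), 0, 1)}, zero elsewhere.}
#'   \item{unstable}{degradation-tagged reporter,
#'     \code{g0 * (1 + g1 * z) * stable}.}
#'   \item{beads}{bright 2 x 2 x 1 substrate beads at the base plane, outside
#'     the colony footprint.}
#' }
#' Noise (Poisson shot noise on signal + background, then Gaussian read
#' noise) is applied last. Identical specs give bitwise-identical output.
#'
#' @param spec a \linkS4class{SyntheticColonySpec}.
#' @param channels which channels to render (subset of stable, dead,
#'   unstable, beads, in any order).
#' @param competition if TRUE, voxels are additionally labeled strain 1 with
#'   probability \code{mixFraction} (else strain 2) and channels
#'   \code{strain1}/\code{strain2} split the stable signal accordingly.
#' @return list with elements \code{image} (\linkS4class{VoxelImage}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
renderColony <- function(spec,
                         channels = c("stable", "dead", "unstable", "beads"),
                         competition = FALSE) {
    stopifnot(all(channels %in% c("stable", "dead", "unstable", "beads")))
    if (spec@margin < 5)
        stop("grid too small: at least 5 um margin around the dome required")
    vs <- spec@voxelSize
    dx <- vs[1]; dy <- vs[2]; dz <- vs[3]
    nx <- as.integer(ceiling(2 * (spec@R + spec@margin) / dx))
    ny <- as.integer(ceiling(2 * (spec@R + spec@margin) / dy))
    nz <- as.integer(ceiling((spec@H + spec@margin) / dz))
    cx <- nx * dx / 2; cy <- ny * dy / 2
    xs <- (seq_len(nx) - 0.5) * dx
    ys <- (seq_len(ny) - 0.5) * dy
    zc <- (seq_len(nz) - 0.5) * dz
    r2d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
    h2d <- matrix(shapeHeight(as.numeric(r2d), spec), nx, ny)

    mask <- array(FALSE, c(nx, ny, nz))
    for (k in seq_len(nz)) mask[, , k] <- zc[k] < h2d
    if (!any(mask)) stop("invalid spec: dome contains no voxels")

    rGrid <- seq(0, spec@R, by = dx / 2)
    D <- .analyticSurfaceDistance(spec, rGrid, zc)

    dist <- array(NA_real_, c(nx, ny, nz))
    stable0 <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) {
        mk <- mask[, , k]
        if (!any(mk)) next
        dk <- stats::approx(rGrid, D[, k], xout = r2d[mk], rule = 2)$y
        sl <- dist[, , k]; sl[mk] <- dk; dist[, , k] <- sl
        il <- stable0[, , k]
        il[mk] <- spec@surfaceIntensity * exp(-dk / spec@lambdaDecay)
        stable0[, , k] <- il
    }

    out <- .withSeed(spec@seed, {
        # dead labels: Bernoulli per voxel with height-ramp probability
        dp <- spec@deadParams
        dead <- array(FALSE, c(nx, ny, nz))
        for (k in seq_len(nz)) {
            mk <- mask[, , k]
            if (!any(mk)) next
            p <- dp[3] * min(max((zc[k] - dp[1]) / (dp[2] - dp[1]), 0), 1)
            if (p > 0) {
                sl <- dead[, , k]
                sl[mk] <- stats::runif(sum(mk)) < p
                dead[, , k] <- sl
            }
        }
        strain <- array(0L, c(nx, ny, nz))
        if (competition) {
            strain[mask] <- ifelse(stats::runif(sum(mask)) < spec@mixFraction,
                                   1L, 2L)
        } else strain[mask] <- 1L
        # beads: 2x2x1 blocks in the base plane, outside the footprint
        beads0 <- array(0, c(nx, ny, nz))
        placed <- 0L; attempts <- 0L
        taken <- matrix(FALSE, nx, ny)
        while (placed < spec@nBeads && attempts < 1000L) {
            attempts <- attempts + 1L
            ix <- sample.int(nx - 1L, 1L)
            iy <- sample.int(ny - 1L, 1L)
            rr <- sqrt((xs[ix] - cx)^2 + (ys[iy] - cy)^2)
            if (rr <= spec@R + 2) next
            if (any(taken[ix:(ix + 1L), iy:(iy + 1L)])) next
            beads0[ix:(ix + 1L), iy:(iy + 1L), 1L] <- spec@beadIntensity
            taken[ix:(ix + 1L), iy:(iy + 1L)] <- TRUE
            placed <- placed + 1L
        }
        if (placed < spec@nBeads)
            stop("could not place ", spec@nBeads, " beads outside the footprint")

        g <- spec@ratioParams
        noiseless <- list(stable = stable0, dead = stable0 * dead,
                          beads = beads0)
        if ("unstable" %in% channels) {
            zArr <- array(rep(zc, each = nx * ny), c(nx, ny, nz))
            noiseless$unstable <- g[1] * (1 + g[2] * zArr) * stable0
            rm(zArr)
        }
        if (competition) {
            noiseless$strain1 <- stable0 * (strain == 1L)
            noiseless$strain2 <- stable0 * (strain == 2L)
            channels <- union(channels, c("strain1", "strain2"))
        }
        noiseless <- noiseless[intersect(names(noiseless), channels)]
        noisy <- lapply(noiseless, .applyNoise, noise = spec@noise)
        list(noiseless = noiseless, noisy = noisy, dead = dead,
             strain = strain)
    })

    img <- VoxelImage(out$noisy, vs)
    truth <- new("GroundTruth",
        mask = ColonyMask(mask, vs),
        distance = new("SurfaceDistanceMap", distance = dist,
                       voxelSize = img@voxelSize, includeBase = FALSE),
        noiseless = out$noiseless, deadLabel = out$dead,
        strainLabel = out$strain)
    list(image = img, truth = truth)
}

#' Rasterize only the occupancy mask of a synthetic colony
#'
#' Cheap alternative to \code{\link{renderColony}} when only the geometry is
#' needed (morphometry validation on large flat colonies): builds the exact
#' dome mask without rendering intensity fields or noise.
#'
#' @param spec a \linkS4class{SyntheticColonySpec}.
#' @return a \linkS4class{ColonyMask}.
#' @export
renderMask <- function(spec) {
    vs <- spec@voxelSize
    nx <- as.integer(ceiling(2 * (spec@R + spec@margin) / vs[1]))
    ny <- as.integer(ceiling(2 * (spec@R + spec@margin) / vs[2]))
    nz <- as.integer(ceiling((spec@H + spec@margin) / vs[3]))
    xs <- (seq_len(nx) - 0.5) * vs[1] - nx * vs[1] / 2
    ys <- (seq_len(ny) - 0.5) * vs[2] - ny * vs[2] / 2
    zc <- (seq_len(nz) - 0.5) * vs[3]
    h2d <- matrix(shapeHeight(as.numeric(
        sqrt(outer(xs^2, ys^2, "+"))), spec), nx, ny)
    m <- array(FALSE, c(nx, ny, nz))
    for (k in seq_len(nz)) m[, , k] <- zc[k] < h2d
    if (!any(m)) stop("invalid spec: dome contains no voxels")
    ColonyMask(m, vs)
}

#' Render a 2D overview scan with multiple colony footprints
#'
#' Emulates the whole-filter 2D scan used to find colonies before
#' high-resolution 3D imaging: \code{nColonies} disk footprints of radius
#' \code{spec@R} placed without overlap, plus the spec's noise model.
#'
#' @param nColonies number of colonies (>= 0).
#' @param spec a \linkS4class{SyntheticColonySpec}; R, surfaceIntensity,
#'   noise, voxelSize (x) and seed are used.
#' @param fieldSize side length of the square field (um); default scales
#'   with \code{nColonies}.
#' @return list: \code{image} (2D matrix), \code{centers} (data.frame with
#'   x_um, y_um), \code{pixelSize} (um).
#' @export
renderOverview <- function(nColonies, spec, fieldSize = NULL) {
    stopifnot(nColonies >= 0)
    px <- spec@voxelSize[1]
    if (is.null(fieldSize))
        fieldSize <- max(4 * spec@R,
                         ceiling(sqrt(max(nColonies, 1))) * 3.5 * spec@R)
    n <- as.integer(ceiling(fieldSize / px))
    xs <- (seq_len(n) - 0.5) * px
    .withSeed(spec@seed, {
        centers <- matrix(numeric(0), 0, 2)
        for (i in seq_len(nColonies)) {
            ok <- FALSE
            for (a in seq_len(1000L)) {
                cand <- stats::runif(2, spec@R + 2, fieldSize - spec@R - 2)
                if (nrow(centers) == 0 ||
                    all(sqrt(rowSums((centers - matrix(cand, nrow(centers),
                        2, byrow = TRUE))^2)) > 2 * spec@R + 5)) {
                    ok <- TRUE; break
                }
            }
            if (!ok) stop("cannot place ", nColonies,
                          " non-overlapping colonies in 1000 attempts")
            centers <- rbind(centers, cand)
        }
        img <- matrix(0, n, n)
        for (i in seq_len(nrow(centers))) {
            rr <- sqrt(outer((xs - centers[i, 1])^2,
                             (xs - centers[i, 2])^2, "+"))
            img[rr <= spec@R] <- spec@surfaceIntensity
        }
        img <- .applyNoise(img, spec@noise)
        list(image = img,
             centers = data.frame(x_um = centers[, 1], y_um = centers[, 2]),
             pixelSize = px)
    })
}

#' Render a 2D strain-competition image pair
#'
#' Emulates the competition assay readout: a mixed inoculation spot expands
#' outward; each pixel of the expansion zone belongs to strain 1 with
#' probability \code{spec@mixFraction}, and the two reporter channels carry
#' signal where their strain sits. Noise per the spec's model.
#'
#' @param spec a \linkS4class{SyntheticColonySpec}.
#' @param inoculumRadius radius of the inoculation spot (um).
#' @param expansionWidth width of the colonized zone beyond the inoculum
#'   edge (um); must exceed the ring distance + width to be measurable.
#' @return list: \code{ch1}, \code{ch2} (2D matrices), \code{inoculum}
#'   (logical 2D mask), \code{strainLabel} (0 background / 1 / 2),
#'   \code{pixelSize}, \code{mixFraction}.
#' @export
renderCompetition <- function(spec, inoculumRadius = 100,
                              expansionWidth = 450) {
    px <- spec@voxelSize[1]
    half <- inoculumRadius + expansionWidth + 10
    n <- as.integer(ceiling(2 * half / px))
    xs <- (seq_len(n) - 0.5) * px - half
    rr <- sqrt(outer(xs^2, xs^2, "+"))
    inoc <- rr <= inoculumRadius
    zone <- rr <= inoculumRadius + expansionWidth
    .withSeed(spec@seed, {
        strain <- matrix(0L, n, n)
        strain[zone] <- ifelse(stats::runif(sum(zone)) < spec@mixFraction,
                               1L, 2L)
        ch1 <- .applyNoise(spec@surfaceIntensity * (strain == 1L), spec@noise)
        ch2 <- .applyNoise(spec@surfaceIntensity * (strain == 2L), spec@noise)
        list(ch1 = ch1, ch2 = ch2, inoculum = inoc, strainLabel = strain,
             pixelSize = px, mixFraction = spec@mixFraction)
    })
}
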