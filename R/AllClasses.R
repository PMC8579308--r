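#' @import methods
NULL

#' Calibrated multi-channel 3D intensity grid
#'
#' The universal input container: a named list of 3D intensity arrays sharing
#' one shape, plus the physical voxel size. After ingestion the axial
#' convention is always base (filter side) at z-index 1, so heights above the
#' substrate are \code{(k - 0.5) * dz} micrometres for slice index \code{k}.
#'
#' @slot channels named list of 3D numeric arrays (arbitrary intensity units),
#'   all with identical \code{dim}.
#' @slot voxelSize numeric(3): physical voxel edge lengths (dx, dy, dz) in
#'   micrometres, strictly positive.
#' @export
setClass("VoxelImage",
    representation(channels = "list", voxelSize = "numeric"))

setValidity("VoxelImage", function(object) {
    ch <- object@channels
    if (length(ch) == 0L)
        return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
        return("channels must be named")
    dims <- lapply(ch, dim)
    if (any(vapply(dims, length, 1L) != 3L))
        return("every channel must be a 3D array")
    if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
        return("all channels must share one shape")
    vs <- object@voxelSize
    if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
        return("voxelSize must be three strictly positive values (um)")
    TRUE
})

#' Binary 3D occupancy of colony biomass
#'
#' Aligned voxel-for-voxel with the \linkS4class{VoxelImage} it was derived
#' from; carries the voxel calibration so downstream geometry works in
#' micrometres.
#'
#' @slot mask logical 3D array, TRUE inside the colony.
#' @slot voxelSize numeric(3) voxel size (dx, dy, dz) in micrometres.
#' @export
setClass("ColonyMask",
    representation(mask = "array", voxelSize = "numeric"))

setValidity("ColonyMask", function(object) {
    if (length(dim(object@mask)) != 3L)
        return("mask must be a 3D array")
    if (!is.logical(object@mask))
        return("mask must be logical")
    vs <- object@voxelSize
    if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
        return("voxelSize must be three strictly positive values (um)")
    TRUE
})

#' Per-voxel Euclidean distance to the air-facing colony surface
#'
#' Distances (micrometres) are defined inside the colony mask only and are NA
#' elsewhere; surface voxels carry distance 0. The surface is the set of mask
#' voxels exposed to air: substrate contact at the base plane does not count
#' as surface unless \code{includeBase} was set when computing the map.
#'
#' @slot distance numeric 3D array of distances in micrometres, NA outside
#'   the mask.
#' @slot voxelSize numeric(3) voxel size in micrometres.
#' @slot includeBase logical flag: whether substrate contact counted as
#'   exposed surface.
#' @export
setClass("SurfaceDistanceMap",
    representation(distance = "array", voxelSize = "numeric",
                   includeBase = "logical"))

setValidity("SurfaceDistanceMap", function(object) {
    if (length(dim(object@distance)) != 3L)
        return("distance must be a 3D array")
    d <- object@distance
    if (any(d < 0, na.rm = TRUE))
        return("distances must be non-negative")
    TRUE
})

#' Parameters of a synthetic colony image
#'
#' Defines a dome-shaped axisymmetric colony on a flat substrate together
#' with the reporter fields rendered into it. The default values are the
#' study conditions used throughout the package's recovery tests; see the
#' methods vignette for the rationale behind each.
#'
#' @slot shape character: "power" for h(r) = H (1 - (r/R)^p), or "hemisphere"
#'   for a spherical cap h(r) = sqrt(R^2 - r^2) (validation shape; H must
#'   equal R).
#' @slot H apex height in micrometres.
#' @slot R basal radius in micrometres.
#' @slot bulgeP shape exponent p >= 1 (dimensionless); p = 1 is a cone,
#'   p = 2 a convex bulged dome.
#' @slot lambdaDecay decay length (um) of the stable-reporter intensity with
#'   distance to the air-facing surface (oxygen-dependent chromophore
#'   maturation proxy).
#' @slot surfaceIntensity stable-reporter intensity at the surface (a.u.).
#' @slot deadParams numeric(3) (d0, d1, pmax): per-voxel death probability is
#'   pmax * clamp((z - d0)/(d1 - d0), 0, 1) with z the height (um).
#' @slot ratioParams numeric(2) (g0, g1): unstable/stable reporter ratio is
#'   g0 * (1 + g1 * z).
#' @slot mixFraction strain-1 fraction for competition images, in [0, 1].
#' @slot noise list(poisson_on, read_sigma, background): shot noise switch,
#'   Gaussian read noise sd (a.u.), additive background level (a.u.).
#' @slot voxelSize numeric(3) voxel size (um).
#' @slot margin lateral/axial clearance (um) around the dome in the grid.
#' @slot nBeads number of bright substrate beads rendered at the base plane.
#' @slot beadIntensity bead intensity (a.u.).
#' @slot seed integer random seed controlling all stochastic draws.
#' @export
setClass("SyntheticColonySpec",
    representation(shape = "character", H = "numeric", R = "numeric",
                   bulgeP = "numeric", lambdaDecay = "numeric",
                   surfaceIntensity = "numeric", deadParams = "numeric",
                   ratioParams = "numeric", mixFraction = "numeric",
                   noise = "list", voxelSize = "numeric", margin = "numeric",
                   nBeads = "numeric", beadIntensity = "numeric",
                   seed = "integer"),
    prototype(shape = "power", H = 150, R = 150, bulgeP = 2,
              lambdaDecay = 20, surfaceIntensity = 200,
              deadParams = c(d0 = 50, d1 = 150, pmax = 0.3),
              ratioParams = c(g0 = 0.3, g1 = 0.01),
              mixFraction = 0.5,
              noise = list(poisson_on = TRUE, read_sigma = 2, background = 5),
              voxelSize = c(1, 1, 1), margin = 5,
              nBeads = 12, beadIntensity = 2000, seed = 1L))

setValidity("SyntheticColonySpec", function(object) {
    if (!object@shape %in% c("power", "hemisphere"))
        return("shape must be 'power' or 'hemisphere'")
    if (object@H <= 0 || object@R <= 0)
        return("H and R must be positive")
    if (object@shape == "hemisphere" && abs(object@H - object@R) > 1e-9)
        return("hemisphere shape requires H == R")
    if (object@shape == "power" && object@bulgeP < 1)
        return("bulgeP must be >= 1")
    if (object@lambdaDecay <= 0)
        return("lambdaDecay must be positive")
    dp <- object@deadParams
    if (length(dp) != 3L || dp[2] <= dp[1])
        return("deadParams must be (d0, d1, pmax) with d1 > d0")
    if (dp[3] < 0 || dp[3] > 1)
        return("pmax must be in [0, 1]")
    if (object@mixFraction < 0 || object@mixFraction > 1)
        return("mixFraction must be in [0, 1]")
    vs <- object@voxelSize
    if (length(vs) != 3L || any(vs <= 0))
        return("voxelSize must be three positive values (um)")
    no <- object@noise
    if (!all(c("poisson_on", "read_sigma", "background") %in% names(no)))
        return("noise must contain poisson_on, read_sigma, background")
    if (no$read_sigma < 0 || no$background < 0)
        return("read_sigma and background must be non-negative")
    TRUE
})

#' Ground truth accompanying a rendered synthetic colony
#'
#' Stores the noiseless fields and labels used by parameter-recovery tests:
#' the exact occupancy mask, the analytic distance to the air-facing surface
#' (computed from the continuous dome surface, independently of the package's
#' distance transform), the noiseless channel fields, and the per-voxel
#' dead / strain labels.
#'
#' @slot mask \linkS4class{ColonyMask} exact occupancy.
#' @slot distance \linkS4class{SurfaceDistanceMap} analytic surface distance.
#' @slot noiseless named list of noiseless channel arrays (zero outside mask).
#' @slot deadLabel logical 3D array, TRUE at dead voxels (subset of mask).
#' @slot strainLabel integer 3D array (0 outside mask; 1/2 per strain in
#'   competition mode, 1 everywhere inside otherwise).
#' @export
setClass("GroundTruth",
    representation(mask = "ColonyMask", distance = "SurfaceDistanceMap",
                   noiseless = "list", deadLabel = "array",
                   strainLabel = "array"))

setValidity("GroundTruth", function(object) {
    m <- object@mask@mask
    if (any(object@deadLabel & !m))
        return("deadLabel must be a subset of the mask")
    for (f in object@noiseless)
        if (!identical(dim(f), dim(m)))
            return("noiseless fields must match mask shape")
    TRUE
})
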