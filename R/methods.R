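#' Construct a VoxelImage
#'
#' @param channels named list of 3D numeric arrays sharing one shape.
#' @param voxelSize numeric(3): (dx, dy, dz) in micrometres.
#' @return a \linkS4class{VoxelImage}.
#' @examples
#' img <- VoxelImage(list(stable = array(1, c(4, 4, 2))), c(0.5, 0.5, 1))
#' voxelSize(img)
#' @export
VoxelImage <- function(channels, voxelSize) {
    vs <- as.numeric(voxelSize)
    names(vs) <- c("dx", "dy", "dz")
    new("VoxelImage", channels = channels, voxelSize = vs)
}

#' Construct a ColonyMask
#'
#' @param mask logical 3D array.
#' @param voxelSize numeric(3) in micrometres.
#' @return a \linkS4class{ColonyMask}.
#' @export
ColonyMask <- function(mask, voxelSize) {
    storage.mode(mask) <- "logical"
    vs <- as.numeric(voxelSize)
    names(vs) <- c("dx", "dy", "dz")
    new("ColonyMask", mask = mask, voxelSize = vs)
}

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelImage", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ColonyMask", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "SurfaceDistanceMap", function(x) x@voxelSize)

#' @rdname channelNames
#' @export
setMethod("channelNames", "VoxelImage", function(x) names(x@channels))

#' @rdname getChannel
#' @export
setMethod("getChannel", "VoxelImage", function(x, name) {
    if (!name %in% names(x@channels))
        stop("no channel named '", name, "'; available: ",
             paste(names(x@channels), collapse = ", "))
    x@channels[[name]]
})

#' @rdname maskArray
#' @export
setMethod("maskArray", "ColonyMask", function(x) x@mask)

#' @rdname distanceArray
#' @export
setMethod("distanceArray", "SurfaceDistanceMap", function(x) x@distance)

setMethod("show", "VoxelImage", function(object) {
    d <- dim(object@channels[[1]])
    cat("VoxelImage:", paste(d, collapse = " x "), "voxels,",
        length(object@channels), "channel(s)\n")
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
    cat("  voxel size (um):", paste(signif(object@voxelSize, 4),
        collapse = " x "), "\n")
})

setMethod("show", "ColonyMask", function(object) {
    d <- dim(object@mask)
    n <- sum(object@mask)
    cat("ColonyMask:", paste(d, collapse = " x "), "voxels,",
        n, "occupied (",
        signif(n * prod(object@voxelSize), 6), "um^3 )\n")
})

setMethod("show", "SurfaceDistanceMap", function(object) {
    d <- object@distance
    cat("SurfaceDistanceMap:", paste(dim(d), collapse = " x "),
        "voxels; range",
        paste(signif(range(d, na.rm = TRUE), 4), collapse = " - "),
        "um;", if (object@includeBase) "base included as surface"
        else "air-facing surface only", "\n")
})

setMethod("show", "SyntheticColonySpec", function(object) {
    cat("SyntheticColonySpec:", object@shape, "colony, H =", object@H,
        "um, R =", object@R, "um",
        if (object@shape == "power") paste0("(p = ", object@bulgeP, ")"),
        "\n")
    cat("  lambda =", object@lambdaDecay, "um, surface intensity =",
        object@surfaceIntensity, "a.u.\n")
    cat("  dead ramp (d0, d1, pmax):",
        paste(object@deadParams, collapse = ", "), "\n")
    cat("  ratio params (g0, g1):",
        paste(object@ratioParams, collapse = ", "), "\n")
    no <- object@noise
    cat("  noise: poisson =", no$poisson_on, ", read sigma =", no$read_sigma,
        ", background =", no$background, "; seed =", object@seed, "\n")
})
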