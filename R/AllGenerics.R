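#' Voxel calibration accessor
#'
#' @param x a \linkS4class{VoxelImage}, \linkS4class{ColonyMask} or
#'   \linkS4class{SurfaceDistanceMap}.
#' @return numeric(3): voxel edge lengths (dx, dy, dz) in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Channel names of a VoxelImage
#' @param x a \linkS4class{VoxelImage}.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel as a 3D array
#' @param x a \linkS4class{VoxelImage}.
#' @param name channel name.
#' @return 3D numeric array.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' Logical occupancy array of a ColonyMask
#' @param x a \linkS4class{ColonyMask}.
#' @return logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Distance array of a SurfaceDistanceMap
#' @param x a \linkS4class{SurfaceDistanceMap}.
#' @return numeric 3D array (um), NA outside the colony mask.
#' @export
setGeneric("distanceArray", function(x) standardGeneric("distanceArray"))
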