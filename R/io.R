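`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a VoxelImage as a multi-page 32-bit float TIFF with JSON sidecar
#'
#' Pages are written channel-major (all z-slices of the first channel, then
#' the second, ...), base plane first. TIFF float pages are stored rescaled
#' to [0, 1]; the per-channel offset/scale, voxel calibration, channel names
#' and z orientation go into a JSON sidecar (\code{<path>.json}) read back
#' by \code{\link{readStack}}.
#'
#' @param image a \linkS4class{VoxelImage}.
#' @param path output TIFF path.
#' @return invisibly, the sidecar metadata list.
#' @export
writeStack <- function(image, path) {
    chn <- channelNames(image)
    pages <- list()
    scale <- list()
    for (ch in chn) {
        arr <- getChannel(image, ch)
        lo <- min(arr); hi <- max(arr)
        sc <- if (hi > lo) hi - lo else 1
        scale[[ch]] <- list(offset = lo, scale = sc)
        for (k in seq_len(dim(arr)[3]))
            pages[[length(pages) + 1L]] <- (arr[, , k] - lo) / sc
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    meta <- list(format = "colonyvox-stack-1",
                 voxel_size_um = as.numeric(voxelSize(image)),
                 channels = as.list(chn),
                 n_z = dim(getChannel(image, chn[1]))[3],
                 z_orientation = "base_at_0",
                 page_order = "z_within_channel",
                 channel_scale = scale)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(meta)
}

# Minimal OME-XML metadata extraction (namespace-agnostic): voxel physical
# sizes, SizeC/SizeZ, DimensionOrder, channel names.
.parseOME <- function(desc) {
    doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
    if (is.null(doc)) return(NULL)
    px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
    if (inherits(px, "xml_missing")) return(NULL)
    a <- function(n) {
        v <- xml2::xml_attr(px, n)
        if (is.na(v)) NULL else v
    }
    vs <- c(a("PhysicalSizeX"), a("PhysicalSizeY"), a("PhysicalSizeZ"))
    chNodes <- xml2::xml_find_all(doc, "//*[local-name()='Channel']")
    chn <- xml2::xml_attr(chNodes, "Name")
    nC <- as.integer(a("SizeC") %||% max(length(chNodes), 1L))
    if (length(chn) == 0 || any(is.na(chn)))
        chn <- paste0("ch", seq_len(nC))
    list(voxel_size_um = if (length(vs) == 3) as.numeric(vs) else NULL,
         channels = as.list(chn),
         n_z = if (!is.null(a("SizeZ"))) as.integer(a("SizeZ")) else NULL,
         page_order = if (identical(a("DimensionOrder"), "XYCZT"))
             "channel_within_z" else "z_within_channel",
         z_orientation = NULL,
         channel_scale = NULL)
}

#' Read a multi-page TIFF / OME-TIFF stack into a VoxelImage
#'
#' Metadata (voxel calibration, channel names, page order, z orientation)
#' come from the JSON sidecar written by \code{\link{writeStack}} when
#' present, else from OME-XML in the TIFF description; a
#' \code{\link{runConfig}} can override calibration, channel names and
#' orientation. Missing calibration with no override is an error, never a
#' silent default. Output is always in the canonical orientation with the
#' base (filter side) at z-index 1; stacks recorded apex-first (e.g. imaged
#' facing down on an inverted microscope) are flipped at ingestion.
#'
#' @param path TIFF file path.
#' @param config optional \code{\link{runConfig}} with overrides
#'   (\code{voxelSize}, \code{channelNames}, \code{zOrientation}).
#' @return a \linkS4class{VoxelImage}.
#' @export
readStack <- function(path, config = NULL) {
    if (!file.exists(path)) stop("cannot read file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    npages <- length(pages)
    meta <- NULL
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
        meta$voxel_size_um <- as.numeric(unlist(meta$voxel_size_um))
        meta$n_z <- if (!is.null(meta$n_z)) as.integer(meta$n_z[[1]])
    } else {
        desc <- attr(pages[[1]], "description")
        if (!is.null(desc) && grepl("<", desc, fixed = TRUE))
            meta <- .parseOME(desc)
    }
    voxelSize <- config$voxelSize %||% meta$voxel_size_um
    if (is.null(voxelSize) || length(voxelSize) != 3)
        stop("missing voxel calibration: no usable metadata and no ",
             "config override")
    chn <- config$channelNames %||% unlist(meta$channels) %||% "ch1"
    nc <- length(chn)
    nz <- meta$n_z %||% (npages %/% nc)
    if (nc * nz != npages)
        stop("channel count mismatch: ", npages, " pages cannot hold ",
             nc, " channel(s) of ", nz, " slice(s)")
    order <- meta$page_order %||% "z_within_channel"
    channels <- list()
    for (ci in seq_len(nc)) {
        pidx <- if (order == "channel_within_z")
            (seq_len(nz) - 1L) * nc + ci
        else (ci - 1L) * nz + seq_len(nz)
        arr <- simplify2array(lapply(pages[pidx], unclass))
        if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
        sc <- meta$channel_scale[[chn[ci]]]
        if (!is.null(sc))
            arr <- arr * as.numeric(sc$scale) + as.numeric(sc$offset)
        channels[[chn[ci]]] <- arr
    }
    zo <- config$zOrientation %||% meta$z_orientation %||% "base_at_0"
    if (identical(zo, "apex_at_0"))
        channels <- lapply(channels, function(a) a[, , rev(seq_len(nz)),
                                                   drop = FALSE])
    img <- VoxelImage(channels, voxelSize)
    if (!is.null(config$channels)) {
        roles <- config$channels[!is.na(config$channels)]
        missing <- roles[!roles %in% names(channels)]
        if (length(missing))
            stop("configured channel role(s) not present in file: ",
                 paste(names(missing), "->", missing, collapse = ", "))
    }
    img
}

#' Write a result table as CSV (units embedded in column names)
#'
#' One header row; values at full double precision so that a write/read
#' round trip is lossless to better than 1e-9 relative.
#'
#' @param records a data.frame (any profile/metric table).
#' @param path output CSV path.
#' @export
writeResultTable <- function(records, path) {
    stopifnot(is.data.frame(records))
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}

#' Read back a result table written by \code{\link{writeResultTable}}
#' @param path CSV path.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
    if (!file.exists(path)) stop("cannot read file: ", path)
    utils::read.csv(path)
}
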