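#' Build a run configuration
#'
#' Central parameter object for \code{\link{runPipeline}} and
#' \code{\link{readStack}}. All lengths are micrometres. Defaults follow the
#' measurement conventions the package implements: 30 um oxic shell, ratio
#' comparison heights 100 and 0 um, competition ring at 350 um distance and
#' 35 um width, 3.3 um axial cylinder, 2 um distance shells.
#'
#' @param channels named character vector mapping channel roles
#'   (stable_reporter, dead_stain, unstable_reporter, beads) to channel
#'   names in the image; set a role to NA to mark it absent.
#' @param voxelSize optional numeric(3) calibration override (um).
#' @param channelNames optional channel names override for files without
#'   channel metadata.
#' @param zOrientation optional "base_at_0" or "apex_at_0" override.
#' @param smoothSigma segmentation pre-smoothing sigma (pixels).
#' @param gradientThreshold fixed gradient threshold; NULL for per-slice
#'   Otsu.
#' @param minSliceArea minimum segmented area per slice (um^2).
#' @param shellBinWidth distance-shell width (um).
#' @param oxicShellDepth oxic shell depth (um).
#' @param profileHeights numeric(2) (high, low) heights for the ratiometric
#'   fold-change (um).
#' @param ratioBinWidth height bin width (um) for the ratio.
#' @param heightBin height bin width (um) for the viability profile.
#' @param cylRadius axial cylinder radius (um).
#' @param ringDistance,ringWidth competition ring geometry (um).
#' @param includeBase count substrate contact as surface in the distance
#'   map.
#' @param analyses "all" or a subset of c("biovolume", "morphology",
#'   "profiles", "viability", "growth").
#' @param seed integer seed recorded in provenance and used for any
#'   stochastic stage.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(channels = c(stable_reporter = "stable",
                                   dead_stain = "dead",
                                   unstable_reporter = "unstable",
                                   beads = "beads"),
                      voxelSize = NULL, channelNames = NULL,
                      zOrientation = NULL,
                      smoothSigma = 1, gradientThreshold = NULL,
                      minSliceArea = 20,
                      shellBinWidth = 2, oxicShellDepth = 30,
                      profileHeights = c(100, 0), ratioBinWidth = 5,
                      heightBin = 10, cylRadius = 3.3,
                      ringDistance = 350, ringWidth = 35,
                      includeBase = FALSE, analyses = "all", seed = 1L) {
    stopifnot(shellBinWidth > 0, oxicShellDepth > 0, heightBin > 0,
              ratioBinWidth > 0, cylRadius > 0, ringDistance >= 0,
              ringWidth > 0, length(profileHeights) == 2)
    if (!is.null(voxelSize) && (length(voxelSize) != 3 ||
                                any(voxelSize <= 0)))
        stop("voxelSize override must be three positive values (um)")
    known <- c("biovolume", "morphology", "profiles", "viability", "growth")
    if (!identical(analyses, "all") && !all(analyses %in% known))
        stop("unknown analyses: ",
             paste(setdiff(analyses, known), collapse = ", "))
    structure(list(channels = channels, voxelSize = voxelSize,
                   channelNames = channelNames, zOrientation = zOrientation,
                   smoothSigma = smoothSigma,
                   gradientThreshold = gradientThreshold,
                   minSliceArea = minSliceArea,
                   shellBinWidth = shellBinWidth,
                   oxicShellDepth = oxicShellDepth,
                   profileHeights = profileHeights,
                   ratioBinWidth = ratioBinWidth, heightBin = heightBin,
                   cylRadius = cylRadius, ringDistance = ringDistance,
                   ringWidth = ringWidth, includeBase = includeBase,
                   analyses = analyses, seed = as.integer(seed)),
              class = "RunConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.role <- function(config, role) {
    ch <- config$channels[role]
    if (is.null(ch) || is.na(ch)) NULL else unname(ch)
}

#' Run the full analysis pipeline on one stack
#'
#' Executes segment, distance map, morphometry, depth profiles and (when the
#' needed channel roles are present) viability and ratiometric growth
#' analyses, writing one CSV per result table plus \code{metrics.json} and a
#' \code{provenance.json} record (configuration, seed, package version,
#' input checksum). Identical configuration and input produce byte-identical
#' outputs.
#'
#' @param input path to a multi-page TIFF / OME-TIFF stack.
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with all in-memory results and the paths
#'   written.
#' @export
runPipeline <- function(input, config = runConfig(), outDir) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    analyses <- config$analyses

    img <- .stage("read", readStack(input, config))
    chn <- channelNames(img)
    stableCh <- .role(config, "stable_reporter") %||% chn[1]
    deadCh <- .role(config, "dead_stain")
    unstableCh <- .role(config, "unstable_reporter")
    if (identical(analyses, "all")) {
        analyses <- c("biovolume", "morphology", "profiles",
                      if (!is.null(deadCh) && deadCh %in% chn) "viability",
                      if (!is.null(unstableCh) && unstableCh %in% chn)
                          "growth")
    }
    if ("viability" %in% analyses && (is.null(deadCh) || !deadCh %in% chn))
        stop("analysis 'viability' requires channel role 'dead_stain', ",
             "which is not mapped to any channel in the image")
    if ("growth" %in% analyses && (is.null(unstableCh) ||
                                   !unstableCh %in% chn))
        stop("analysis 'growth' requires channel role 'unstable_reporter', ",
             "which is not mapped to any channel in the image")

    results <- list()
    paths <- character(0)
    putTable <- function(tab, name) {
        p <- file.path(outDir, paste0(name, ".csv"))
        writeResultTable(tab, p)
        paths[[name]] <<- p
    }
    metrics <- list()

    bio <- .stage("segment", biovolume(img, channel = stableCh,
        smoothSigma = config$smoothSigma,
        threshold = config$gradientThreshold,
        minSliceArea = config$minSliceArea))
    mask <- bio$mask
    results$biovolume <- bio
    metrics$biovolume_um3 <- bio$biovolume_um3
    putTable(bio$perSlice, "slice_areas")

    dmap <- .stage("distance_map",
                   surfaceDistanceMap(mask, includeBase = config$includeBase))
    results$distmap <- dmap

    if ("morphology" %in% analyses) {
        mm <- .stage("morphology",
            morphologyMetrics(mask, hQuery = config$profileHeights[1]))
        results$morphology <- mm
        metrics$height_um <- mm$height_um
        metrics$radius_um <- mm$radius_um
        metrics$slope_at_height <- mm$slope_at_height
        putTable(mm$profile, "height_radius_profile")
    }

    if ("profiles" %in% analyses) {
        .stage("profiles", {
            corr <- subtractBackground(img, mask, stableCh)
            shp <- shellProfile(corr, dmap, binWidth = config$shellBinWidth,
                                channel = stableCh)
            putTable(shp, "shell_profile")
            results$shellProfile <- shp
            fit <- tryCatch(fitDecayLength(shp), error = function(e) NULL)
            metrics$lambda_um <- if (is.null(fit)) NA else fit$lambda_um
            metrics$lambda_r_squared <- if (is.null(fit)) NA
                else fit$r_squared
            axp <- axialCylinderProfile(corr, mask, channel = stableCh,
                                        cylRadius = config$cylRadius)
            putTable(axp, "axial_profile")
            results$axialProfile <- axp
            bpp <- basalPlaneProfile(corr, mask, channel = stableCh,
                                     binWidth = config$shellBinWidth)
            putTable(bpp, "basal_profile")
            results$basalProfile <- bpp
            ff <- fluorescentFraction(img, mask, channel = stableCh)
            metrics$fluorescent_fraction <- as.numeric(ff)
        })
    }

    if ("viability" %in% analyses) {
        vp <- .stage("viability", deadFractionProfile(img, mask, dmap,
            stableChannel = stableCh, deadChannel = deadCh,
            shellDepth = config$oxicShellDepth,
            heightBin = config$heightBin))
        results$viability <- vp
        metrics$mean_dead_fraction <-
            mean(vp$dead_fraction, na.rm = TRUE)
        putTable(vp, "viability_profile")
    }

    if ("growth" %in% analyses) {
        gr <- .stage("growth", reporterRatioFoldChange(img, mask, dmap,
            unstableChannel = unstableCh, stableChannel = stableCh,
            hHi = config$profileHeights[1], hLo = config$profileHeights[2],
            shellDepth = config$oxicShellDepth,
            binWidth = config$ratioBinWidth))
        results$growth <- gr
        metrics$ratio_fold_change <- gr$fold_change
        putTable(gr$table, "ratio_profile")
    }

    mp <- file.path(outDir, "metrics.json")
    jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths[["metrics"]] <- mp

    prov <- list(package = "colonyvox",
                 version = as.character(utils::packageVersion("colonyvox")),
                 input = basename(input),
                 input_md5 = unname(tools::md5sum(input)),
                 seed = config$seed,
                 analyses = analyses,
                 config = unclass(config))
    pp <- file.path(outDir, "provenance.json")
    jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths[["provenance"]] <- pp

    invisible(c(results, list(metrics = metrics, paths = paths,
                              image = img, mask = mask)))
}
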