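# End-to-end measurement of one angiogram and batch processing.

#' Measure one angiogram end to end
#'
#' Runs the full pipeline: binarization ([binarizeAngiogram()]), density-map
#' lesion localization, lesion area and vascular perfusion density,
#' skeletonization, box-counting fractal dimension and gliding-box
#' lacunarity. Degenerate downstream stages (e.g. a skeleton too small for
#' a dimension fit) yield `NaN` metrics with explanatory flags rather than
#' an error; a degenerate input image (constant intensity) is an error.
#'
#' @param image an [AngiogramImage-class].
#' @param config an [AnalysisConfig-class].
#' @param details also return the intermediate objects.
#' @return a [LesionMeasurement-class]; with `details = TRUE`, a list with
#'   `measurement`, `mask`, `dmap`, `region`, `skeleton`, `fit`, `lacres`.
#' @export
analyzeAngiogram <- function(image, config = analysisConfig(),
                             details = FALSE) {
  mask <- binarizeAngiogram(image, config)
  flags <- character(0)
  nFg <- sum(pixels(mask))
  if (nFg == 0L) {
    measurement <- new("LesionMeasurement", sourceId = image@sourceId,
                       areaMm2 = 0, vpd = 0, fd = NaN, fdR2 = NaN, lac = NaN,
                       nForegroundPx = 0L, flags = "empty_mask")
    if (!details) return(measurement)
    return(list(measurement = measurement, mask = mask, dmap = NULL,
                region = NULL, skeleton = NULL, fit = NULL, lacres = NULL))
  }
  dmap <- densityMap(mask, config@densityKernelPx)
  region <- highestDensityZone(dmap, mask, config@zoneLevel)
  areaMm2 <- lesionArea(region, mmPerPixel(image))
  vpd <- vascularPerfusionDensity(
    mask, if (config@vpdRegion == "lesion") region else NULL)
  skel <- skeletonize(mask)
  fit <- tryCatch(fractalDimension(skel, config), error = function(e) {
    flags <<- c(flags, "degenerate_fd_fit"); NULL
  })
  lacres <- tryCatch(lacunarity(skel, config), error = function(e) {
    flags <<- c(flags, "degenerate_lacunarity"); NULL
  })
  measurement <- new("LesionMeasurement", sourceId = image@sourceId,
                     areaMm2 = areaMm2, vpd = vpd,
                     fd = if (is.null(fit)) NaN else fit@fd,
                     fdR2 = if (is.null(fit)) NaN else fit@fdR2,
                     lac = if (is.null(lacres)) NaN else lacres@lac,
                     nForegroundPx = as.integer(nFg), flags = flags)
  if (!details) return(measurement)
  list(measurement = measurement, mask = mask, dmap = dmap, region = region,
       skeleton = skel, fit = fit, lacres = lacres)
}

#' Measure a batch of angiogram files
#'
#' Per-image failures (e.g. a constant image with no Otsu threshold) are
#' collected as error records and the batch continues.
#'
#' @param paths character vector of PNG/TIFF paths.
#' @param mmPerPixel pixel scale applied to every image.
#' @param config an [AnalysisConfig-class].
#' @param quiet suppress per-image progress messages.
#' @return list with `measurements` (list of [LesionMeasurement-class]) and
#'   `errors` (data.frame of source_id, error).
#' @export
analyzeBatch <- function(paths, mmPerPixel, config = analysisConfig(),
                         quiet = FALSE) {
  measurements <- list()
  errors <- list()
  for (path in paths) {
    sid <- sub("\\.[^.]*$", "", basename(path))
    res <- tryCatch({
      img <- readAngiogram(path, mmPerPixel)
      analyzeAngiogram(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!quiet) message("ERROR  ", sid, ": ", conditionMessage(res))
      errors[[length(errors) + 1L]] <- data.frame(
        source_id = sid, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      if (!quiet)
        message(sprintf("OK     %s: area %.4f mm^2, vpd %.4f, fd %.4f",
                        sid, res@areaMm2, res@vpd, res@fd))
      measurements[[length(measurements) + 1L]] <- res
    }
  }
  list(measurements = measurements,
       errors = if (length(errors)) do.call(rbind, errors) else NULL)
}
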