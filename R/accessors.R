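#' @describeIn pixels intensities of an angiogram
#' @export
setMethod("pixels", "AngiogramImage", function(x) x@pixels)

#' @describeIn pixels logical pixels of a mask
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @describeIn mmPerPixel scale of an angiogram
#' @export
setMethod("mmPerPixel", "AngiogramImage", function(x) x@mmPerPixel)

#' @describeIn mmPerPixel scale of a mask
#' @export
setMethod("mmPerPixel", "BinaryMask", function(x) x@mmPerPixel)

#' @describeIn provenance steps applied to a mask
#' @export
setMethod("provenance", "BinaryMask", function(x) x@provenance)

#' @describeIn maskMetadata metadata of a mask
#' @export
setMethod("maskMetadata", "BinaryMask", function(x) x@metadata)

#' @describeIn fd of a fit
#' @export
setMethod("fd", "FractalFit", function(x) x@fd)

#' @describeIn fd of a measurement
#' @export
setMethod("fd", "LesionMeasurement", function(x) x@fd)

#' @describeIn lac of a lacunarity result
#' @export
setMethod("lac", "LacunarityResult", function(x) x@lac)

#' @describeIn lac of a measurement
#' @export
setMethod("lac", "LesionMeasurement", function(x) x@lac)

#' @describeIn pValue of a two-sample comparison
#' @export
setMethod("pValue", "GroupComparison", function(x) x@pValue)

setMethod("show", "AngiogramImage", function(object) {
  p <- object@pixels
  cat(sprintf("AngiogramImage '%s': %d x %d px, %.4g mm/px, range [%g, %g]\n",
              object@sourceId, nrow(p), ncol(p), object@mmPerPixel,
              min(p), max(p)))
})

setMethod("show", "BinaryMask", function(object) {
  p <- object@pixels
  cat(sprintf("%s: %d x %d px, %d foreground (%.1f%%), %.4g mm/px\n",
              class(object), nrow(p), ncol(p), sum(p),
              100 * mean(p), object@mmPerPixel))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d x %d, kernel %d px, max density %.3f\n",
              nrow(object@values), ncol(object@values), object@kernelPx,
              max(object@values)))
})

setMethod("show", "LesionRegion", function(object) {
  cat(sprintf("LesionRegion: %d px, centroid (%.1f, %.1f)\n",
              object@areaPx, object@centroid[1], object@centroid[2]))
})

setMethod("show", "FractalFit", function(object) {
  cat(sprintf("FractalFit: fd = %.4f (R^2 = %.4f) over %d box sizes [%d..%d]\n",
              object@fd, object@fdR2, length(object@boxSizesPx),
              min(object@boxSizesPx), max(object@boxSizesPx)))
})

setMethod("show", "LacunarityResult", function(object) {
  cat(sprintf("LacunarityResult: lac = %.4f over %d box sizes\n",
              object@lac, length(object@boxSizesPx)))
})

setMethod("show", "LesionMeasurement", function(object) {
  cat(sprintf(
    "LesionMeasurement '%s': area %.4f mm^2, VPD %.4f, FD %.4f (R^2 %.3f), LAC %.4f\n",
    object@sourceId, object@areaMm2, object@vpd, object@fd, object@fdR2,
    object@lac))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison (%s): %s (n=%g, %.3f +/- %.3f) vs %s (n=%g, %.3f +/- %.3f)\n  t = %.4f, df = %.2f, p = %.4g\n",
    object@variant, object@groupLabels[1], object@n[1], object@groupMean[1],
    object@groupSd[1], object@groupLabels[2], object@n[2], object@groupMean[2],
    object@groupSd[2], object@tStatistic, object@df, object@pValue))
})

setMethod("show", "AnalysisConfig", function(object) {
  b <- object@boxSizesPx
  cat("AnalysisConfig:\n",
      sprintf("  median radius %d px (%s, %s domain)\n", object@medianRadiusPx,
              if (object@squareMedian) "square" else "disk",
              if (object@grayscaleMedian) "grayscale" else "binary"),
      sprintf("  min component %d px, connectivity %d\n",
              object@minComponentPx, object@connectivity),
      sprintf("  box sizes: %s; %d origins (%s)\n",
              if (length(b) == 1L && is.na(b)) "auto (powers of 2)"
              else paste(b, collapse = ","),
              object@nGridOrigins, object@originMode),
      sprintf("  density kernel %d px, zone level %.2f, VPD region '%s'\n",
              object@densityKernelPx, object@zoneLevel, object@vpdRegion),
      sep = "")
})
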