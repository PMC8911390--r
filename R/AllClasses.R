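#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib octafract, .registration = TRUE
NULL

#' AngiogramImage: a 2-D grayscale en-face angiogram
#'
#' Container for a single en-face OCT-A slab: a matrix of non-negative
#' integer-valued intensities together with the physical pixel scale
#' (isotropic, mm per pixel) that converts pixel counts into lesion areas.
#' Intensities are kept on their native scale (a 16-bit export is not
#' rescaled to 8-bit).
#'
#' @slot pixels numeric matrix of finite, non-negative intensities.
#' @slot mmPerPixel positive scalar, millimetres per pixel (isotropic).
#' @slot sourceId opaque identifier carried through to results.
#' @exportClass AngiogramImage
setClass("AngiogramImage",
  representation(pixels = "matrix", mmPerPixel = "numeric",
                 sourceId = "character"),
  prototype(mmPerPixel = 0.01, sourceId = "unknown"))

setValidity("AngiogramImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 16L || ncol(p) < 16L)
    return("image must be at least 16 x 16 pixels")
  if (any(!is.finite(p))) return("intensities must be finite")
  if (any(p < 0)) return("intensities must be non-negative")
  if (length(object@mmPerPixel) != 1L || !is.finite(object@mmPerPixel) ||
      object@mmPerPixel <= 0)
    return("mmPerPixel must be a positive scalar")
  if (length(object@sourceId) != 1L) return("sourceId must be a single string")
  TRUE
})

#' BinaryMask: a boolean vessel mask
#'
#' Result of binarizing an [AngiogramImage-class]. Carries the pixel scale,
#' the ordered provenance of processing steps applied so far, and free-form
#' metadata (synthetic generators record e.g. the theoretical fractal
#' dimension of a fixture here).
#'
#' @slot pixels logical matrix.
#' @slot mmPerPixel positive scalar, millimetres per pixel.
#' @slot provenance character vector of applied step names, in call order.
#' @slot metadata named list of generator/analysis annotations.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", mmPerPixel = "numeric",
                 provenance = "character", metadata = "list"),
  prototype(mmPerPixel = 0.01, provenance = character(0), metadata = list()))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (anyNA(object@pixels)) return("mask may not contain NA")
  if (length(object@mmPerPixel) != 1L || !is.finite(object@mmPerPixel) ||
      object@mmPerPixel <= 0)
    return("mmPerPixel must be a positive scalar")
  TRUE
})

#' SkeletonMask: one-pixel-wide skeleton of a vessel mask
#'
#' A [BinaryMask-class] produced by topology-preserving thinning: the
#' skeleton is a subset of its source mask and has the same number of
#' 8-connected components.
#'
#' @exportClass SkeletonMask
setClass("SkeletonMask", contains = "BinaryMask")

#' DensityMap: local foreground fraction of a mask
#'
#' @slot values numeric matrix in \[0, 1\]; each entry is the foreground
#'   fraction of the mask within the square kernel window centered there
#'   (borders handled by symmetric reflection).
#' @slot kernelPx odd positive integer, kernel side length in pixels.
#' @exportClass DensityMap
setClass("DensityMap",
  representation(values = "matrix", kernelPx = "integer"))

setValidity("DensityMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("values must lie in [0, 1]")
  if (object@kernelPx < 1L || object@kernelPx %% 2L == 0L)
    return("kernelPx must be a positive odd integer")
  TRUE
})

#' LesionRegion: the highest-density zone of a mask
#'
#' A single connected region of the analyzed slab containing the density-map
#' argmax, used as the lesion footprint for area measurement.
#'
#' @slot regionMask logical matrix (single connected component).
#' @slot centroid numeric (row, col) centroid of the region, in pixels.
#' @slot areaPx integer pixel count of the region.
#' @exportClass LesionRegion
setClass("LesionRegion",
  representation(regionMask = "matrix", centroid = "numeric",
                 areaPx = "integer"))

setValidity("LesionRegion", function(object) {
  if (!is.logical(object@regionMask)) return("regionMask must be logical")
  if (object@areaPx != sum(object@regionMask))
    return("areaPx must equal the regionMask pixel count")
  if (length(object@centroid) != 2L) return("centroid must be (row, col)")
  TRUE
})

#' AnalysisConfig: tunable parameters of the measurement pipeline
#'
#' Defaults reproduce the published processing parameters: a median filter
#' of radius 2 pixels and removal of connected components smaller than 10
#' pixels. See [analysisConfig()] for the constructor with argument
#' documentation.
#'
#' @slot medianRadiusPx disk radius of the despeckling majority filter.
#' @slot minComponentPx minimum surviving component size, in pixels.
#' @slot boxSizesPx strictly increasing integer box sizes (>= 2) for box
#'   counting; `NA` means "powers of two from 2 to min(H, W)/4" at use time.
#' @slot nGridOrigins number of grid origins for multi-origin box counting.
#' @slot densityKernelPx odd kernel side for the density map.
#' @slot connectivity 4 or 8, pixel connectivity for component labeling.
#' @slot zoneLevel fraction of the density maximum delimiting the lesion zone.
#' @slot vpdRegion "slab" or "lesion": normalization region for VPD.
#' @slot originMode "mean" or "min": aggregation of counts over origins.
#' @slot grayscaleMedian apply the median filter to the grayscale image
#'   before thresholding instead of to the binary mask after it.
#' @slot squareMedian use a square (side 2r+1) window instead of a disk.
#' @slot randomSeed integer seed or NA.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(medianRadiusPx = "integer", minComponentPx = "integer",
                 boxSizesPx = "integer", nGridOrigins = "integer",
                 densityKernelPx = "integer", connectivity = "integer",
                 zoneLevel = "numeric", vpdRegion = "character",
                 originMode = "character", grayscaleMedian = "logical",
                 squareMedian = "logical", randomSeed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (object@medianRadiusPx < 1L) return("medianRadiusPx must be >= 1")
  if (object@minComponentPx < 1L) return("minComponentPx must be >= 1")
  b <- object@boxSizesPx
  if (!(length(b) == 1L && is.na(b))) {
    if (any(is.na(b)) || any(b < 2L)) return("box sizes must be >= 2")
    if (length(b) > 1L && any(diff(b) <= 0L))
      return("box sizes must be strictly increasing")
  }
  if (object@nGridOrigins < 1L) return("nGridOrigins must be >= 1")
  if (object@densityKernelPx < 1L || object@densityKernelPx %% 2L == 0L)
    return("densityKernelPx must be a positive odd integer")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (object@zoneLevel <= 0 || object@zoneLevel >= 1)
    return("zoneLevel must lie in (0, 1)")
  if (!object@vpdRegion %in% c("slab", "lesion"))
    return("vpdRegion must be 'slab' or 'lesion'")
  if (!object@originMode %in% c("mean", "min"))
    return("originMode must be 'mean' or 'min'")
  TRUE
})

#' FractalFit: diagnostics of a box-counting dimension fit
#'
#' @slot boxSizesPx increasing integer box sizes used.
#' @slot counts per-size mean occupied-box counts over grid origins.
#' @slot fd fractal dimension, minus the slope of log(count) vs log(size).
#' @slot fdR2 coefficient of determination of the log-log fit.
#' @slot nOriginsUsed per-size number of grid origins averaged.
#' @exportClass FractalFit
setClass("FractalFit",
  representation(boxSizesPx = "integer", counts = "numeric", fd = "numeric",
                 fdR2 = "numeric", nOriginsUsed = "integer"))

setValidity("FractalFit", function(object) {
  if (length(object@counts) != length(object@boxSizesPx))
    return("counts and boxSizesPx lengths differ")
  if (any(object@counts <= 0)) return("counts must be positive")
  if (length(object@counts) > 1L && any(diff(object@counts) > 1e-9))
    return("counts must be non-increasing in box size")
  if (is.finite(object@fdR2) && (object@fdR2 < -1e-9 || object@fdR2 > 1 + 1e-9))
    return("fdR2 must lie in [0, 1]")
  TRUE
})

#' LacunarityResult: gliding-box lacunarity curve and aggregate
#'
#' @slot boxSizesPx integer gliding-box sizes.
#' @slot lambdaPerSize lacunarity Lambda(r) = E\[M^2\]/E\[M\]^2 per size, each >= 1.
#' @slot lac aggregate lacunarity (unweighted mean of Lambda(r)).
#' @exportClass LacunarityResult
setClass("LacunarityResult",
  representation(boxSizesPx = "integer", lambdaPerSize = "numeric",
                 lac = "numeric"))

setValidity("LacunarityResult", function(object) {
  if (length(object@lambdaPerSize) != length(object@boxSizesPx))
    return("lambdaPerSize and boxSizesPx lengths differ")
  if (any(object@lambdaPerSize < 1 - 1e-9))
    return("lacunarity must be >= 1 at every size")
  TRUE
})

#' LesionMeasurement: per-eye quantitative OCT-A record
#'
#' The four published lesion metrics (area in mm^2, vascular perfusion
#' density as a fraction, box-counting fractal dimension, gliding-box
#' lacunarity) plus fit diagnostics. A degenerate fit is stored as `NaN`
#' with an explanatory flag.
#'
#' @slot sourceId identifier of the analyzed image.
#' @slot areaMm2 lesion area, mm^2.
#' @slot vpd vascular perfusion density, fraction in \[0, 1\].
#' @slot fd fractal dimension (NaN when the fit is degenerate).
#' @slot fdR2 R^2 of the log-log fit.
#' @slot lac aggregate lacunarity (>= 1, NaN when degenerate).
#' @slot nForegroundPx foreground pixel count of the binarized slab.
#' @slot flags character vector of quality/degeneracy flags.
#' @exportClass LesionMeasurement
setClass("LesionMeasurement",
  representation(sourceId = "character", areaMm2 = "numeric", vpd = "numeric",
                 fd = "numeric", fdR2 = "numeric", lac = "numeric",
                 nForegroundPx = "integer", flags = "character"),
  prototype(flags = character(0)))

setValidity("LesionMeasurement", function(object) {
  if (is.finite(object@areaMm2) && object@areaMm2 < 0)
    return("areaMm2 must be >= 0")
  if (is.finite(object@vpd) && (object@vpd < 0 || object@vpd > 1))
    return("vpd must lie in [0, 1]")
  if (is.finite(object@lac) && object@lac < 1 - 1e-9)
    return("lac must be >= 1")
  TRUE
})

#' GroupComparison: a two-sample location test
#'
#' @slot groupLabels labels of the two groups compared.
#' @slot n per-group sample sizes.
#' @slot groupMean,groupSd per-group summary statistics.
#' @slot tStatistic,df,pValue two-sided t-test results.
#' @slot variant "welch" or "student".
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(groupLabels = "character", n = "numeric",
                 groupMean = "numeric", groupSd = "numeric",
                 tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 variant = "character"))

setValidity("GroupComparison", function(object) {
  if (object@df <= 0) return("df must be positive")
  if (object@pValue < 0 || object@pValue > 1) return("p-value must lie in [0,1]")
  if (!object@variant %in% c("student", "welch"))
    return("variant must be 'student' or 'welch'")
  TRUE
})
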