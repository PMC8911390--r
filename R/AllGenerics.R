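#' Pixel data of an image-like object
#' @param x an AngiogramImage, BinaryMask or SkeletonMask.
#' @return the underlying matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Physical pixel scale (mm per pixel)
#' @param x an image-like object.
#' @return positive scalar.
#' @export
setGeneric("mmPerPixel", function(x) standardGeneric("mmPerPixel"))

#' Ordered provenance of processing steps
#' @param x a BinaryMask or SkeletonMask.
#' @return character vector of step names in call order.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Generator/analysis metadata attached to a mask
#' @param x a BinaryMask or SkeletonMask.
#' @return named list.
#' @export
setGeneric("maskMetadata", function(x) standardGeneric("maskMetadata"))

#' Estimated fractal dimension
#' @param x a FractalFit or LesionMeasurement.
#' @return numeric scalar (NaN for a degenerate fit).
#' @export
setGeneric("fd", function(x) standardGeneric("fd"))

#' Aggregate lacunarity
#' @param x a LacunarityResult or LesionMeasurement.
#' @return numeric scalar >= 1.
#' @export
setGeneric("lac", function(x) standardGeneric("lac"))

#' Two-sided p-value of a comparison
#' @param x a GroupComparison.
#' @return numeric scalar in \[0, 1\].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
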