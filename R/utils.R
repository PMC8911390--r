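# Internal helpers shared across modules.

stopValidation <- function(...) {
  stop(structure(class = c("octafract_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stopDegenerate <- function(...) {
  stop(structure(class = c("octafract_degenerate_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stopInput <- function(...) {
  stop(structure(class = c("octafract_input_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# Evaluate expr with a locally set RNG seed, restoring global RNG state.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Symmetric (reflect-including-edge) padding of a matrix by `r` on all sides.
padSymmetric <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  if (r > H || r > W) stopValidation("padding radius %d exceeds image extent", r)
  ri <- c(r:1, 1:H, H:(H - r + 1L))
  ci <- c(r:1, 1:W, W:(W - r + 1L))
  m[ri, ci, drop = FALSE]
}

# All r x r window sums of a numeric matrix via an integral image.
# Returns an (H-r+1) x (W-r+1) matrix.
windowSums <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(r >= 1L, r <= H, r <= W)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  S[(r + 1L):(H + 1L), (r + 1L):(W + 1L), drop = FALSE] -
    S[1L:(H - r + 1L), (r + 1L):(W + 1L), drop = FALSE] -
    S[(r + 1L):(H + 1L), 1L:(W - r + 1L), drop = FALSE] +
    S[1L:(H - r + 1L), 1L:(W - r + 1L), drop = FALSE]
}

# Round half away from zero, the convention used for printed percentages.
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

asCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x))
    stopValidation("%s must be a positive integer", name)
  as.integer(x)
}

#' Construct an analysis configuration
#'
#' Defaults reproduce the published processing parameters: despeckling with
#' a median (majority) filter of radius 2 pixels and removal of connected
#' components smaller than 10 pixels. Remaining parameters are unstated in
#' the source protocol and are fixed here to documented defaults.
#'
#' @param medianRadiusPx disk radius (pixels) of the despeckling filter.
#' @param minComponentPx components smaller than this many pixels are removed.
#' @param boxSizesPx integer vector of box sizes for box counting, strictly
#'   increasing, each >= 2. `NA` (default) selects powers of two from 2 up to
#'   min(height, width)/4 of the analyzed image.
#' @param nGridOrigins number of grid origins for multi-origin box counting;
#'   at each size r, a deterministic stratified lattice of
#'   min(r^2, nGridOrigins) offsets in \[0, r)^2 is used.
#' @param densityKernelPx odd side length of the density-map window.
#' @param connectivity 4 or 8 (default), pixel connectivity.
#' @param zoneLevel fraction of the maximum density delimiting the
#'   highest-density zone.
#' @param vpdRegion "slab" (default) or "lesion": denominator region for
#'   vascular perfusion density.
#' @param originMode "mean" (default) or "min" aggregation of occupied-box
#'   counts over grid origins.
#' @param grayscaleMedian apply the median filter to grayscale input before
#'   thresholding rather than to the binary mask after it.
#' @param squareMedian use a square window instead of a disk.
#' @param randomSeed integer seed recorded in run manifests, or NA.
#' @return an [AnalysisConfig-class] object.
#' @examples
#' analysisConfig()
#' analysisConfig(minComponentPx = 20, connectivity = 4)
#' @export
analysisConfig <- function(medianRadiusPx = 2L, minComponentPx = 10L,
                           boxSizesPx = NA, nGridOrigins = 16L,
                           densityKernelPx = 15L, connectivity = 8L,
                           zoneLevel = 0.5, vpdRegion = c("slab", "lesion"),
                           originMode = c("mean", "min"),
                           grayscaleMedian = FALSE, squareMedian = FALSE,
                           randomSeed = NA) {
  vpdRegion <- match.arg(vpdRegion)
  originMode <- match.arg(originMode)
  new("AnalysisConfig",
      medianRadiusPx = asCount(medianRadiusPx, "medianRadiusPx"),
      minComponentPx = asCount(minComponentPx, "minComponentPx"),
      boxSizesPx = if (length(boxSizesPx) == 1L && is.na(boxSizesPx))
        NA_integer_ else as.integer(boxSizesPx),
      nGridOrigins = asCount(nGridOrigins, "nGridOrigins"),
      densityKernelPx = asCount(densityKernelPx, "densityKernelPx"),
      connectivity = as.integer(connectivity),
      zoneLevel = zoneLevel, vpdRegion = vpdRegion, originMode = originMode,
      grayscaleMedian = isTRUE(grayscaleMedian),
      squareMedian = isTRUE(squareMedian),
      randomSeed = if (is.na(randomSeed)) NA_integer_ else as.integer(randomSeed))
}

#' Construct an angiogram image from a matrix
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param mmPerPixel positive isotropic pixel scale, mm/pixel.
#' @param sourceId identifier carried into results.
#' @return an [AngiogramImage-class].
#' @examples
#' img <- angiogramImage(matrix(0:255, 16, 16), mmPerPixel = 0.01)
#' @export
angiogramImage <- function(pixels, mmPerPixel, sourceId = "unknown") {
  if (!is.matrix(pixels)) stopValidation("pixels must be a matrix")
  new("AngiogramImage", pixels = pixels, mmPerPixel = as.numeric(mmPerPixel),
      sourceId = as.character(sourceId))
}

#' Construct a binary mask from a logical matrix
#'
#' @param pixels logical matrix.
#' @param mmPerPixel positive pixel scale, mm/pixel.
#' @param provenance character vector of step names already applied.
#' @param metadata named list of annotations.
#' @return a [BinaryMask-class].
#' @examples
#' binaryMask(matrix(c(TRUE, FALSE), 8, 8))
#' @export
binaryMask <- function(pixels, mmPerPixel = 0.01, provenance = character(0),
                       metadata = list()) {
  new("BinaryMask", pixels = pixels, mmPerPixel = as.numeric(mmPerPixel),
      provenance = provenance, metadata = metadata)
}

# Default box-size ladder: powers of two from 2 to min(H, W)/4.
defaultBoxSizes <- function(H, W) {
  top <- min(H, W) / 4
  if (top < 2) stopValidation("image too small for box counting")
  as.integer(2^(1:floor(log2(top))))
}

resolveBoxSizes <- function(config, H, W) {
  b <- config@boxSizesPx
  if (length(b) == 1L && is.na(b)) return(defaultBoxSizes(H, W))
  if (max(b) > min(H, W) / 2)
    stopValidation("largest box size %d exceeds half the image extent", max(b))
  b
}
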