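# Lesion localization via a density map, lesion area in mm^2, and
# vascular perfusion density (VPD).

#' Local vessel density map
#'
#' Each value is the mean of the binary mask over the `kernelPx` x
#' `kernelPx` window centered at the pixel, with symmetric reflection at
#' the borders, so values lie in \[0, 1\] and the map mean equals the
#' overall foreground fraction.
#'
#' @param mask a [BinaryMask-class].
#' @param kernelPx positive odd window side, pixels.
#' @return a [DensityMap-class].
#' @export
densityMap <- function(mask, kernelPx = 15L) {
  kernelPx <- asCount(kernelPx, "kernelPx")
  if (kernelPx %% 2L == 0L) stopValidation("kernelPx must be odd")
  m <- pixels(mask)
  if (kernelPx > min(nrow(m), ncol(m)))
    stopValidation("kernel %d exceeds image extent", kernelPx)
  h <- (kernelPx - 1L) %/% 2L
  vals <- if (h == 0L) m * 1 else
    windowSums(padSymmetric(m * 1, h), kernelPx) / kernelPx^2
  new("DensityMap", values = vals, kernelPx = kernelPx)
}

#' Highest-density zone of a vessel mask
#'
#' Thresholds the density map at `level` times its maximum and returns the
#' connected component (8-connectivity) of that super-level set containing
#' the density argmax (first maximum in column-major order on ties). This
#' region is the lesion footprint used for area measurement.
#'
#' @param dmap a [DensityMap-class] for `mask`.
#' @param mask the [BinaryMask-class] the map was computed from.
#' @param level fraction of the maximum density, in (0, 1), default 0.5.
#' @return a [LesionRegion-class].
#' @export
highestDensityZone <- function(dmap, mask, level = 0.5) {
  if (!any(pixels(mask))) stopDegenerate("empty mask: no lesion zone")
  if (level <= 0 || level >= 1) stopValidation("level must lie in (0, 1)")
  v <- dmap@values
  peak <- which.max(v)
  sel <- v >= level * max(v)
  lab <- .label_components_cpp(sel, 8L)
  region <- lab == lab[peak]
  idx <- which(region, arr.ind = TRUE)
  new("LesionRegion", regionMask = region,
      centroid = c(mean(idx[, 1L]), mean(idx[, 2L])),
      areaPx = as.integer(nrow(idx)))
}

#' Lesion area in mm^2
#'
#' @param region a [LesionRegion-class].
#' @param mmPerPixel positive pixel scale, mm/pixel.
#' @return area in mm^2 (`areaPx * mmPerPixel^2`).
#' @examples
#' # 10,000 px at 0.01 mm/px -> 1 mm^2
#' @export
lesionArea <- function(region, mmPerPixel) {
  if (!is.numeric(mmPerPixel) || mmPerPixel <= 0)
    stopValidation("mmPerPixel must be positive")
  region@areaPx * mmPerPixel^2
}

#' Vascular perfusion density
#'
#' Fraction of perfused (mask-foreground) pixels within a region of
#' measurement: the whole analyzed slab by default, or the lesion region.
#' Reported as a fraction in \[0, 1\]; it is independent of the physical
#' pixel scale.
#'
#' @param mask a [BinaryMask-class].
#' @param region a [LesionRegion-class], or NULL for the whole slab.
#' @return numeric fraction in \[0, 1\].
#' @export
vascularPerfusionDensity <- function(mask, region = NULL) {
  m <- pixels(mask)
  if (is.null(region)) return(mean(m))
  inside <- region@regionMask
  if (!any(inside)) stopDegenerate("empty region of measurement")
  sum(m & inside) / sum(inside)
}
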