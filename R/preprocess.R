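# Binarization of a grayscale angiogram into a clean vessel mask:
# Otsu thresholding, median (majority) despeckling, small-component removal.

#' Otsu threshold of an angiogram
#'
#' Builds a 256-bin histogram over the observed intensity range and selects
#' the cut maximizing the between-class variance, computed from the exact
#' class means (bin-sum based, so for 8-bit data the result is identical to
#' exhaustive search over all integer cut points). Ties are broken toward
#' the lower threshold. The returned threshold is the largest intensity
#' assigned to the background class; the mask is `intensity > threshold`.
#'
#' @param image an [AngiogramImage-class] with at least 2 distinct values.
#' @return list with `threshold` (numeric) and `mask` ([BinaryMask-class]).
#' @examples
#' img <- angiogramImage(matrix(rep(c(10, 200), each = 128), 16, 16), 0.01)
#' otsuThreshold(img)$threshold
#' @export
otsuThreshold <- function(image) {
  v <- as.vector(pixels(image))
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stopDegenerate("constant image: no Otsu threshold exists")
  nb <- 256L
  bin <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  sums <- numeric(nb)
  bySum <- rowsum(v, bin) # rows ordered by sorted unique bin
  sums[sort(unique(bin))] <- bySum[, 1L]
  n <- length(v); S <- sum(v)
  w0 <- cumsum(counts)[-nb]
  s0 <- cumsum(sums)[-nb]
  valid <- w0 > 0 & w0 < n
  mu0 <- s0 / w0
  mu1 <- (S - s0) / (n - w0)
  bcv <- ifelse(valid, w0 * (n - w0) * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv) # which.max returns the first (lowest) maximizer
  threshold <- max(v[bin <= k])
  mask <- binaryMask(matrix(v > threshold, nrow(pixels(image))),
                     mmPerPixel = mmPerPixel(image),
                     provenance = "otsu_threshold")
  list(threshold = threshold, mask = mask)
}

diskOffsets <- function(radius, square = FALSE) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  if (!square) d <- d[d$dy^2 + d$dx^2 <= radius^2, ]
  d
}

#' Median (majority) despeckling of a binary mask
#'
#' Each output pixel takes the majority value of the mask within a
#' disk-shaped neighborhood of the given radius (a square window is
#' available for comparison). Borders are handled by symmetric reflection.
#' A tie (possible only for square windows of even pixel count, which
#' cannot occur here) would resolve to background.
#'
#' @param mask a [BinaryMask-class].
#' @param radiusPx neighborhood radius in pixels (default 2).
#' @param square use a (2r+1) x (2r+1) square window instead of a disk.
#' @return despeckled [BinaryMask-class].
#' @examples
#' m <- binaryMask(matrix(FALSE, 32, 32)); m@pixels[16, 16] <- TRUE
#' sum(pixels(medianDespeckle(m)))  # isolated speckle removed -> 0
#' @export
medianDespeckle <- function(mask, radiusPx = 2L, square = FALSE) {
  radiusPx <- asCount(radiusPx, "radiusPx")
  m <- pixels(mask)
  H <- nrow(m); W <- ncol(m)
  if (radiusPx > floor(min(H, W) / 2))
    stopValidation("radius %d exceeds half the image extent", radiusPx)
  off <- diskOffsets(radiusPx, square = square)
  pm <- padSymmetric(m * 1L, radiusPx)
  acc <- matrix(0L, H, W)
  for (k in seq_len(nrow(off))) {
    acc <- acc + pm[(1:H) + radiusPx + off$dy[k],
                    (1:W) + radiusPx + off$dx[k], drop = FALSE]
  }
  out <- 2L * acc > nrow(off)
  binaryMask(out, mmPerPixel = mmPerPixel(mask),
             provenance = c(provenance(mask), "median_despeckle"),
             metadata = maskMetadata(mask))
}

#' Label connected foreground components
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix of component labels (0 = background), labelled in
#'   column-major discovery order.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  m <- if (is(mask, "BinaryMask")) pixels(mask) else mask
  if (!connectivity %in% c(4L, 8L)) stopValidation("connectivity must be 4 or 8")
  .label_components_cpp(m, as.integer(connectivity))
}

#' Remove small connected components
#'
#' Every connected foreground component with fewer than `minSizePx` pixels
#' is set to background; larger components are left untouched, so the
#' operation is idempotent and never increases the foreground.
#'
#' @param mask a [BinaryMask-class].
#' @param minSizePx minimum surviving component size (default 10 pixels).
#' @param connectivity 4 or 8 (default).
#' @return filtered [BinaryMask-class].
#' @export
removeSmallComponents <- function(mask, minSizePx = 10L, connectivity = 8L) {
  minSizePx <- asCount(minSizePx, "minSizePx")
  lab <- labelComponents(mask, connectivity)
  m <- pixels(mask)
  if (any(lab > 0L)) {
    sizes <- tabulate(lab)
    drop <- which(sizes < minSizePx)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  binaryMask(m, mmPerPixel = mmPerPixel(mask),
             provenance = c(provenance(mask), "remove_small_components"),
             metadata = maskMetadata(mask))
}

#' Full binarization pipeline
#'
#' Otsu thresholding, then median despeckling, then small-component removal,
#' in the published order. With `grayscaleMedian` in the config, the median
#' filter is instead applied to the grayscale image before thresholding.
#'
#' @param image an [AngiogramImage-class].
#' @param config an [AnalysisConfig-class]; defaults reproduce the published
#'   parameters (radius 2, minimum component 10 px).
#' @return a [BinaryMask-class] with full provenance.
#' @export
binarizeAngiogram <- function(image, config = analysisConfig()) {
  validObject(config)
  if (config@grayscaleMedian) {
    r <- config@medianRadiusPx
    off <- diskOffsets(r, square = config@squareMedian)
    pm <- padSymmetric(pixels(image), r)
    H <- nrow(pixels(image)); W <- ncol(pixels(image))
    sh <- vapply(seq_len(nrow(off)), function(k)
      as.vector(pm[(1:H) + r + off$dy[k], (1:W) + r + off$dx[k], drop = FALSE]),
      numeric(H * W))
    med <- matrix(apply(sh, 1L, stats::median), H, W)
    image <- angiogramImage(med, mmPerPixel(image), image@sourceId)
    mask <- otsuThreshold(image)$mask
    mask@provenance <- c("median_despeckle_grayscale", mask@provenance)
  } else {
    mask <- otsuThreshold(image)$mask
    mask <- medianDespeckle(mask, config@medianRadiusPx,
                            square = config@squareMedian)
  }
  removeSmallComponents(mask, config@minComponentPx, config@connectivity)
}
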