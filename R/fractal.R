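# Multi-origin box-counting fractal dimension and gliding-box lacunarity.

# Deterministic stratified lattice of grid origins in [0, r)^2:
# g = floor(sqrt(min(r^2, nOrigins))) offsets per axis, evenly spaced.
gridOrigins <- function(r, nOrigins) {
  g <- max(1L, floor(sqrt(min(r^2, nOrigins))))
  off <- unique(floor(r * (0:(g - 1L)) / g))
  expand.grid(dy = off, dx = off)
}

#' Occupied-box count at one box size, averaged over grid origins
#'
#' For each origin offset the image is circularly shifted by (dy, dx), the
#' plane is tiled with r x r boxes anchored at the image corner, and boxes
#' containing at least one foreground pixel are counted. Circular (periodic)
#' shifts make the count exactly unbiased under translation of the pattern;
#' the mean (or minimum) over origins is returned.
#'
#' @param skel a [SkeletonMask-class] or [BinaryMask-class].
#' @param r box size in pixels, `2 <= r <= min(H, W)/2`.
#' @param origins data.frame with columns `dy`, `dx` of offsets in \[0, r),
#'   or NULL for the default stratified lattice.
#' @param nOrigins lattice budget when `origins` is NULL.
#' @param mode aggregate over origins by "mean" (default) or "min".
#' @return list with `count` (aggregate), `perOrigin` (numeric vector) and
#'   `nOrigins`.
#' @export
boxCount <- function(skel, r, origins = NULL, nOrigins = 16L,
                     mode = c("mean", "min")) {
  mode <- match.arg(mode)
  m <- pixels(skel)
  H <- nrow(m); W <- ncol(m)
  if (!any(m)) stopDegenerate("empty skeleton: nothing to count")
  if (r < 2L || r > min(H, W) / 2)
    stopValidation("box size %d outside [2, min extent/2]", r)
  if (is.null(origins)) origins <- gridOrigins(r, nOrigins)
  if (any(origins$dy < 0 | origins$dy >= r | origins$dx < 0 | origins$dx >= r))
    stopValidation("origin offsets must lie in [0, r)^2")
  idx <- which(m, arr.ind = TRUE)
  i0 <- idx[, 1L] - 1L; j0 <- idx[, 2L] - 1L
  nbw <- ceiling(W / r)
  per <- vapply(seq_len(nrow(origins)), function(k) {
    bi <- ((i0 + origins$dy[k]) %% H) %/% r
    bj <- ((j0 + origins$dx[k]) %% W) %/% r
    length(unique(bi * nbw + bj))
  }, numeric(1))
  count <- if (mode == "mean") mean(per) else min(per)
  list(count = count, perOrigin = per, nOrigins = nrow(origins))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes at each configured size (multi-origin, see
#' [boxCount()]) and fits an ordinary least-squares line to log(count)
#' versus log(size) over all configured sizes; the fractal dimension is
#' minus the slope. No automatic linear-range selection is performed.
#'
#' @param skel a [SkeletonMask-class] (or any [BinaryMask-class]) with at
#'   least 10 foreground pixels.
#' @param config an [AnalysisConfig-class]; box sizes default to powers of
#'   two from 2 to min(H, W)/4.
#' @return a [FractalFit-class].
#' @examples
#' line <- makeFractal("line", 256)
#' fd(fractalDimension(line))  # ~1
#' @export
fractalDimension <- function(skel, config = analysisConfig()) {
  m <- pixels(skel)
  if (sum(m) < 10L)
    stopDegenerate("skeleton has fewer than 10 foreground pixels")
  sizes <- resolveBoxSizes(config, nrow(m), ncol(m))
  sizes <- sizes[sizes >= 2L & sizes <= min(dim(m)) / 2]
  if (length(sizes) < 2L)
    stopValidation("need at least 2 usable box sizes")
  res <- lapply(sizes, function(r)
    boxCount(skel, r, nOrigins = config@nGridOrigins,
             mode = config@originMode))
  counts <- vapply(res, `[[`, numeric(1), "count")
  # enforce monotonicity against counting noise at non-divisor sizes
  counts <- rev(cummax(rev(counts)))
  x <- log(sizes); y <- log(counts)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ssRes <- sum((y - intercept - slope * x)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot <= .Machine$double.eps) 1 else max(0, 1 - ssRes / ssTot)
  fdHat <- -slope
  if (fdHat < -0.05 || fdHat > 2.05)
    warning("fractal dimension estimate ", round(fdHat, 3),
            " outside the planar range [0, 2]")
  new("FractalFit", boxSizesPx = as.integer(sizes), counts = counts,
      fd = fdHat, fdR2 = r2,
      nOriginsUsed = vapply(res, function(z) as.integer(z$nOrigins),
                            integer(1)))
}

#' Gliding-box lacunarity
#'
#' For each box size r, an r x r window glides at unit step over all
#' positions fully inside the image; with M the foreground mass per window,
#' Lambda(r) = E\[M^2\] / E\[M\]^2 (>= 1, equal to 1 only for spatially
#' uniform mass). The aggregate `lac` is the unweighted mean of Lambda(r)
#' over the configured box-size set; the full curve is always returned.
#'
#' @param skel a [SkeletonMask-class] or [BinaryMask-class], nonempty.
#' @param config an [AnalysisConfig-class] (box sizes as for
#'   [fractalDimension()]).
#' @return a [LacunarityResult-class].
#' @export
lacunarity <- function(skel, config = analysisConfig()) {
  m <- pixels(skel)
  if (!any(m)) stopDegenerate("empty skeleton: lacunarity undefined")
  sizes <- resolveBoxSizes(config, nrow(m), ncol(m))
  sizes <- sizes[sizes <= min(dim(m))]
  lam <- vapply(sizes, function(r) glidingBoxLacunarity(skel, r), numeric(1))
  new("LacunarityResult", boxSizesPx = as.integer(sizes),
      lambdaPerSize = lam, lac = mean(lam))
}

#' Lacunarity at a single gliding-box size
#'
#' @param skel a [SkeletonMask-class] or [BinaryMask-class], nonempty.
#' @param r window side in pixels, `1 <= r <= min(H, W)`.
#' @return Lambda(r) = E\[M^2\]/E\[M\]^2 over all fully-inside windows.
#' @export
glidingBoxLacunarity <- function(skel, r) {
  m <- if (is(skel, "BinaryMask")) pixels(skel) else skel
  if (!any(m)) stopDegenerate("empty skeleton: lacunarity undefined")
  if (r < 1L || r > min(dim(m)))
    stopValidation("window size %d outside [1, min extent]", r)
  M <- as.vector(windowSums(m * 1, r))
  mu <- mean(M)
  mean(M^2) / mu^2
}
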