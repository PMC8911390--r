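# Topology-preserving thinning of the binary vessel mask to a one-pixel
# skeleton, and simple skeleton diagnostics.

#' Skeletonize a binary mask
#'
#' Sequential topology-preserving thinning: border pixels are peeled in
#' four directional subcycles (north, south, east, west), deleting only
#' "simple" pixels (whose removal changes neither the 8-connected
#' foreground nor the 4-connected background topology of their 3x3
#' neighborhood) that are not endpoints. Consequently the skeleton is a
#' subset of the source mask, has exactly the same number of 8-connected
#' components, and the operation is idempotent.
#'
#' @param mask a [BinaryMask-class].
#' @return a [SkeletonMask-class].
#' @export
skeletonize <- function(mask) {
  skel <- .thin_cpp(pixels(mask))
  new("SkeletonMask", pixels = skel, mmPerPixel = mmPerPixel(mask),
      provenance = c(provenance(mask), "skeletonize"),
      metadata = maskMetadata(mask))
}

skeletonNeighborCounts <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m * 1L
  acc <- matrix(0L, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc + p[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx, drop = FALSE]
  }
  acc
}

#' Skeleton length and topology diagnostics
#'
#' Length uses the unit-pixel approximation (foreground count times the
#' pixel scale); set `diagonalCorrection` to weight diagonal steps by
#' sqrt(2). Branchpoints are skeleton pixels with at least 3 skeleton
#' neighbors, endpoints those with exactly 1.
#'
#' @param skel a [SkeletonMask-class].
#' @param mmPerPixel pixel scale; defaults to the skeleton's own.
#' @param diagonalCorrection apply the sqrt(2) diagonal-step correction.
#' @return list with `length_mm`, `n_branchpoints`, `n_endpoints`.
#' @export
skeletonStats <- function(skel, mmPerPixel = NULL, diagonalCorrection = FALSE) {
  m <- pixels(skel)
  if (is.null(mmPerPixel)) mmPerPixel <- mmPerPixel(skel)
  if (!any(m))
    return(list(length_mm = 0, n_branchpoints = 0L, n_endpoints = 0L))
  nb <- skeletonNeighborCounts(m)
  lengthPx <- if (!diagonalCorrection) sum(m) else {
    H <- nrow(m); W <- ncol(m)
    p <- matrix(FALSE, H + 2L, W + 2L); p[2:(H + 1L), 2:(W + 1L)] <- m
    straight <- sum(p[2:(H + 1L), 2:(W + 1L)] & p[3:(H + 2L), 2:(W + 1L)]) +
      sum(p[2:(H + 1L), 2:(W + 1L)] & p[2:(H + 1L), 3:(W + 2L)])
    diag <- sum(p[2:(H + 1L), 2:(W + 1L)] & p[3:(H + 2L), 3:(W + 2L)]) +
      sum(p[2:(H + 1L), 2:(W + 1L)] & p[3:(H + 2L), 1:W])
    # edge-weighted path length; isolated pixels count 1
    straight + sqrt(2) * diag + sum(m & nb == 0L)
  }
  list(length_mm = lengthPx * mmPerPixel,
       n_branchpoints = sum(m & nb >= 3L),
       n_endpoints = sum(m & nb == 1L))
}
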