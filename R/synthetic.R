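# Synthetic inputs used to validate every stage: canonical fractals of
# known dimension, branching vascular networks with optional polyp-like
# terminal dilations and multiplicative speckle, and cohort tables.
# Every generator is a pure function of its parameters and seed.

#' Canonical binary fractal fixtures of known dimension
#'
#' Deterministic rasters whose theoretical box-counting dimension is known:
#' a one-pixel line (1), a filled square (2), the Sierpinski triangle
#' (log 3/log 2 ~ 1.585), the Sierpinski carpet (log 8/log 3 ~ 1.893), and
#' random Cantor dust (quadtree subdivision keeping each quadrant with
#' probability `retention`; expected dimension 2 + log2(retention)). The
#' theoretical dimension is attached under `maskMetadata(x)$theoreticalDim`.
#'
#' @param name one of "line", "filled_square", "sierpinski_triangle",
#'   "sierpinski_carpet", "random_cantor_dust".
#' @param sizePx image side, >= 64.
#' @param depth recursion depth; must be feasible for `sizePx` (cell grid
#'   2^depth, or 3^depth for the carpet, must fit).
#' @param seed RNG seed, used only by the random dust.
#' @param retention per-quadrant retention probability of the dust.
#' @param mmPerPixel pixel scale attached to the mask.
#' @return a [BinaryMask-class] of size `sizePx` x `sizePx`.
#' @examples
#' tri <- makeFractal("sierpinski_triangle", 256, depth = 7)
#' maskMetadata(tri)$theoreticalDim  # log(3)/log(2)
#' @export
makeFractal <- function(name = c("line", "filled_square",
                                 "sierpinski_triangle", "sierpinski_carpet",
                                 "random_cantor_dust"),
                        sizePx = 256L, depth = 5L, seed = 1L,
                        retention = 0.7, mmPerPixel = 0.01) {
  name <- match.arg(name)
  sizePx <- asCount(sizePx, "sizePx")
  if (sizePx < 64L) stopValidation("sizePx must be >= 64")
  m <- matrix(FALSE, sizePx, sizePx)
  theo <- NA_real_
  placeCells <- function(cells) {
    n <- nrow(cells)
    u <- sizePx %/% n
    if (u < 1L) stopValidation("depth %d infeasible for size %d", depth, sizePx)
    big <- matrix(FALSE, sizePx, sizePx)
    big[1:(n * u), 1:(n * u)] <- kronecker(cells * 1L, matrix(1L, u, u)) > 0L
    big
  }
  if (name == "line") {
    m[sizePx %/% 2L, ] <- TRUE
    theo <- 1
  } else if (name == "filled_square") {
    m[] <- TRUE
    theo <- 2
  } else if (name == "sierpinski_triangle") {
    n <- 2L^depth
    if (n > sizePx) stopValidation("depth %d infeasible for size %d", depth, sizePx)
    idx <- 0:(n - 1L)
    cells <- outer(idx, idx, function(a, b) bitwAnd(a, b) == 0L)
    m <- placeCells(cells)
    theo <- log(3) / log(2)
  } else if (name == "sierpinski_carpet") {
    n <- 3L^depth
    if (n > sizePx) stopValidation("depth %d infeasible for size %d", depth, sizePx)
    idx <- 0:(n - 1L)
    digitsOk <- function(a, b) {
      ok <- rep(TRUE, length(a))
      aa <- a; bb <- b
      for (l in seq_len(depth)) {
        ok <- ok & !(aa %% 3L == 1L & bb %% 3L == 1L)
        aa <- aa %/% 3L; bb <- bb %/% 3L
      }
      ok
    }
    cells <- outer(idx, idx, digitsOk)
    m <- placeCells(cells)
    theo <- log(8) / log(3)
  } else { # random_cantor_dust
    n <- 2L^depth
    if (n > sizePx) stopValidation("depth %d infeasible for size %d", depth, sizePx)
    cells <- withLocalSeed(seed, {
      keep <- matrix(TRUE, 1L, 1L)
      for (l in seq_len(depth)) {
        keep <- kronecker(keep, matrix(TRUE, 2L, 2L)) &
          matrix(stats::runif(4^l) < retention, 2L^l, 2L^l)
      }
      keep
    })
    m <- placeCells(cells)
    theo <- 2 + log2(retention)
  }
  binaryMask(m, mmPerPixel = mmPerPixel,
             provenance = paste0("make_fractal:", name),
             metadata = list(theoreticalDim = theo, depth = depth, name = name))
}

#' Parameters of the synthetic branching vascular network
#'
#' Defaults emulate a choroidal branching vascular network on a 3 x 3 mm
#' en-face slab sampled at 256 px (0.01 mm/px after modest downsampling):
#' a trunk entering from the image edge whose tips bifurcate with
#' probability `branchProb` (and otherwise continue growing) over `levels`
#' generations, with geometric length decay and angular jitter, rasterized
#' at a 3 px vessel caliber. Polyp-like
#' aneurysmal dilations can be stamped on terminal tips, and the grayscale
#' render uses foreground/background means of 180/30 (8-bit) with
#' multiplicative log-normal speckle of sigma `speckleSigma`.
#'
#' @param imagePx image side in pixels.
#' @param levels maximum branching depth.
#' @param branchProb probability that a tip bifurcates at each level.
#' @param lengthDecay child-segment length ratio, in (0, 1).
#' @param angleJitterDeg SD of the angular jitter, degrees.
#' @param vesselWidthPx rasterized vessel caliber, pixels.
#' @param polypCount number of polyp-like terminal disks (0 = none).
#' @param polypRadiusPx polyp disk radius, pixels.
#' @param speckleSigma log-normal speckle sigma (0 = noise-free render).
#' @param seed RNG seed.
#' @param mmPerPixel pixel scale attached to outputs.
#' @return validated parameter list of class `VesselSimParams`.
#' @export
vesselSimParams <- function(imagePx = 256L, levels = 10L, branchProb = 0.85,
                            lengthDecay = 0.80, angleJitterDeg = 12,
                            vesselWidthPx = 3L, polypCount = 0L,
                            polypRadiusPx = 5L, speckleSigma = 0.3,
                            seed = 1L, mmPerPixel = 0.01) {
  stopifnot(imagePx >= 64, levels >= 1, branchProb >= 0, branchProb <= 1,
            lengthDecay > 0, lengthDecay < 1, angleJitterDeg >= 0,
            vesselWidthPx >= 1, polypCount >= 0, polypRadiusPx >= 1,
            speckleSigma >= 0)
  structure(list(imagePx = as.integer(imagePx), levels = as.integer(levels),
                 branchProb = branchProb, lengthDecay = lengthDecay,
                 angleJitterDeg = angleJitterDeg,
                 vesselWidthPx = as.integer(vesselWidthPx),
                 polypCount = as.integer(polypCount),
                 polypRadiusPx = as.integer(polypRadiusPx),
                 speckleSigma = speckleSigma, seed = as.integer(seed),
                 mmPerPixel = mmPerPixel),
            class = "VesselSimParams")
}

stampDisk <- function(m, cy, cx, radius) {
  H <- nrow(m); W <- ncol(m)
  ys <- max(1L, floor(cy - radius)):min(H, ceiling(cy + radius))
  xs <- max(1L, floor(cx - radius)):min(W, ceiling(cx + radius))
  for (y in ys) for (x in xs)
    if ((y - cy)^2 + (x - cx)^2 <= radius^2) m[y, x] <- TRUE
  m
}

#' Generate a synthetic branching vascular network
#'
#' Grows a stochastic binary branching tree from the bottom image edge and
#' rasterizes it at the configured caliber; optionally stamps well-separated
#' polyp-like disks on terminal tips and renders a speckled grayscale
#' angiogram (foreground mean 180, background mean 30, multiplicative
#' log-normal speckle). Identical parameters and seed give identical output.
#'
#' @param params a [vesselSimParams()] list.
#' @return list with `clean` (a [BinaryMask-class]; metadata records terminal
#'   tips and polyp centers) and `noisy` (an [AngiogramImage-class]).
#' @export
makeVesselNetwork <- function(params = vesselSimParams()) {
  stopifnot(inherits(params, "VesselSimParams"))
  p <- params
  withLocalSeed(p$seed, {
    H <- W <- p$imagePx
    segs <- list()
    tips <- list()
    grow <- function(y, x, angle, len, level) {
      y2 <- y - len * cos(angle)
      x2 <- x + len * sin(angle)
      segs[[length(segs) + 1L]] <<- c(y, x, y2, x2)
      if (level >= p$levels ||
          y2 < -len || y2 > H + len || x2 < -len || x2 > W + len) {
        tips[[length(tips) + 1L]] <<- c(y2, x2)
        return(invisible(NULL))
      }
      # a neovascular complex is branched by definition: with branching
      # enabled, the first two generations always divide; branchProb
      # governs every later tip
      forced <- level <= 2L && p$branchProb > 0
      if (stats::runif(1) < p$branchProb || forced) {
        # bifurcation: two daughters at +/- the branching spread
        jit <- stats::rnorm(2, 0, p$angleJitterDeg * pi / 180)
        spread <- 25 * pi / 180
        grow(y2, x2, angle - spread + jit[1], len * p$lengthDecay, level + 1L)
        grow(y2, x2, angle + spread + jit[2], len * p$lengthDecay, level + 1L)
      } else {
        # continuation: the vessel keeps growing without dividing
        jit <- stats::rnorm(1, 0, p$angleJitterDeg * pi / 180)
        grow(y2, x2, angle + jit, len * p$lengthDecay, level + 1L)
      }
    }
    grow(H, W / 2, 0, p$imagePx / 5, 1L)
    m <- matrix(FALSE, H, W)
    brushR <- p$vesselWidthPx / 2
    for (s in segs) {
      len <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
      ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5)))
      for (t in ts) {
        cy <- s[1] + t * (s[3] - s[1]); cx <- s[2] + t * (s[4] - s[2])
        if (cy < 1 - brushR || cy > H + brushR ||
            cx < 1 - brushR || cx > W + brushR) next
        m <- stampDisk(m, cy, cx, brushR)
      }
    }
    tipMat <- do.call(rbind, tips)
    inb <- tipMat[, 1] >= 1 & tipMat[, 1] <= H & tipMat[, 2] >= 1 &
      tipMat[, 2] <= W
    tipMat <- tipMat[inb, , drop = FALSE]
    polypCenters <- matrix(numeric(0), 0L, 2L)
    if (p$polypCount > 0L && nrow(tipMat) > 0L) {
      ord <- sample.int(nrow(tipMat))
      minSep <- 2 * p$polypRadiusPx + 2
      for (k in ord) {
        if (nrow(polypCenters) >= p$polypCount) break
        cand <- tipMat[k, ]
        if (cand[1] < p$polypRadiusPx + 1 || cand[1] > H - p$polypRadiusPx ||
            cand[2] < p$polypRadiusPx + 1 || cand[2] > W - p$polypRadiusPx)
          next
        if (nrow(polypCenters) > 0L) {
          d <- sqrt((polypCenters[, 1] - cand[1])^2 +
                    (polypCenters[, 2] - cand[2])^2)
          if (any(d < minSep)) next
        }
        polypCenters <- rbind(polypCenters, cand)
      }
      if (nrow(polypCenters) < p$polypCount)
        warning("placed only ", nrow(polypCenters), " of ", p$polypCount,
                " requested polyps with non-overlapping separation")
      for (k in seq_len(nrow(polypCenters)))
        m <- stampDisk(m, polypCenters[k, 1], polypCenters[k, 2],
                       p$polypRadiusPx)
    }
    clean <- binaryMask(m, mmPerPixel = p$mmPerPixel,
                        provenance = "make_vessel_network",
                        metadata = list(params = unclass(p),
                                        terminalTips = tipMat,
                                        polypCenters = polypCenters))
    base <- ifelse(m, 180, 30)
    noisy <- base * exp(stats::rnorm(H * W, 0, p$speckleSigma))
    noisy <- matrix(pmin(pmax(round(noisy), 0), 255), H, W)
    img <- angiogramImage(noisy, mmPerPixel = p$mmPerPixel,
                          sourceId = sprintf("vessel_seed%d", p$seed))
    list(clean = clean, noisy = img)
  })
}

#' Parameters of the synthetic cohort generator
#'
#' Per-group sample sizes, means and SDs default to the published cohort
#' structure: 40 acute and 62 complex eyes (25 complex without CNV, 11 type
#' 1 CNV, 26 PCV), with age/BCVA summaries from the demographic table and
#' lesion metrics (VPD as a fraction of the printed percent values, FD,
#' LAC, area) from the quantitative table. FD and area are drawn jointly
#' with correlation `trueCorrFdArea` (default, the published r = -0.056).
#'
#' @param groups data.frame with columns `group`, `cscForm`, `cnvType`, `n`,
#'   and `<var>_mean` / `<var>_sd` for var in age, bcva, vpd, fd, lac, area
#'   (NA for groups without lesion metrics).
#' @param trueCorrFdArea correlation between FD and area draws, in \[-1, 1\].
#' @param polypProb probability that a PCV eye shows polyps on OCT-A
#'   (default 20/26, the published correspondence rate).
#' @param seed RNG seed.
#' @return validated parameter list of class `CohortSimParams`.
#' @export
cohortSimParams <- function(groups = NULL, trueCorrFdArea = -0.056,
                            polypProb = 20 / 26, seed = 1L) {
  if (is.null(groups)) {
    groups <- data.frame(
      group = c("acute", "complex_noncnv", "type1", "pcv"),
      cscForm = c("acute", "complex", "complex", "complex"),
      cnvType = c("none", "none", "type1", "pcv"),
      n = c(40L, 25L, 11L, 26L),
      age_mean = c(52.20, 68.27, 65.18, 71.50),
      age_sd = c(9.52, 10, 17.35, 7.79),
      bcva_mean = c(87.06, 79.61, 68, 80.5),
      bcva_sd = c(18.58, 23.32, 39.46, 15.17),
      vpd_mean = c(NA, NA, 0.53, 0.52), vpd_sd = c(NA, NA, 0.23, 0.19),
      fd_mean = c(NA, NA, 1.46, 1.43), fd_sd = c(NA, NA, 0.15, 0.10),
      lac_mean = c(NA, NA, 2.10, 2.53), lac_sd = c(NA, NA, 0.49, 1.26),
      area_mean = c(NA, NA, 2.28, 2.35), area_sd = c(NA, NA, 1.93, 2.16),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(groups$n >= 2), abs(trueCorrFdArea) <= 1)
  sds <- unlist(groups[grep("_sd$", names(groups))])
  stopifnot(all(is.na(sds) | sds > 0))
  structure(list(groups = groups, trueCorrFdArea = trueCorrFdArea,
                 polypProb = polypProb, seed = as.integer(seed)),
            class = "CohortSimParams")
}

#' Generate a synthetic cohort table
#'
#' Draws per-group normal variates with the configured means and SDs; FD
#' and lesion area are drawn jointly with the configured correlation.
#' Normal marginals are used unclipped (so, at the published SDs, a small
#' fraction of draws can be unphysically negative); identical parameters
#' and seed give identical tables.
#'
#' @param params a [cohortSimParams()] list.
#' @return data.frame of eye-level records with columns `eye_id`,
#'   `csc_form`, `cnv_type`, `age_years`, `bcva_letters`, `vpd`, `fd`,
#'   `lac`, `area_mm2`, `polyps_on_octa`.
#' @export
makeCohort <- function(params = cohortSimParams()) {
  stopifnot(inherits(params, "CohortSimParams"))
  g <- params$groups
  rho <- params$trueCorrFdArea
  withLocalSeed(params$seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      draw <- function(var) {
        m <- g[[paste0(var, "_mean")]][i]; s <- g[[paste0(var, "_sd")]][i]
        if (is.na(m)) rep(NA_real_, n) else stats::rnorm(n, m, s)
      }
      age <- draw("age"); bcva <- draw("bcva")
      vpd <- draw("vpd"); lacv <- draw("lac")
      if (!is.na(g$fd_mean[i])) {
        z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
        fdv <- g$fd_mean[i] + g$fd_sd[i] * z1
        areav <- g$area_mean[i] +
          g$area_sd[i] * (rho * z1 + sqrt(1 - rho^2) * z2)
      } else {
        fdv <- rep(NA_real_, n); areav <- rep(NA_real_, n)
      }
      polyps <- if (g$cnvType[i] == "pcv")
        stats::runif(n) < params$polypProb else rep(NA, n)
      data.frame(eye_id = sprintf("%s_%03d", g$group[i], seq_len(n)),
                 csc_form = g$cscForm[i], cnv_type = g$cnvType[i],
                 age_years = age, bcva_letters = bcva, vpd = vpd, fd = fdv,
                 lac = lacv, area_mm2 = areav, polyps_on_octa = polyps,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
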