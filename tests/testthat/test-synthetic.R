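test_that("canonical fractals have their exact self-similar pixel counts", {
  line <- makeFractal("line", 256)
  expect_identical(sum(pixels(line)), 256L)
  expect_identical(length(unique(which(pixels(line), arr.ind = TRUE)[, 1])), 1L)

  square <- makeFractal("filled_square", 128)
  expect_identical(sum(pixels(square)), 128L * 128L)

  carpet <- makeFractal("sierpinski_carpet", 243, depth = 5)
  expect_equal(sum(pixels(carpet)), 8^5)
  # recursive self-similarity: the top-left third equals depth-4 pattern
  sub <- pixels(carpet)[1:81, 1:81]
  expect_equal(sum(sub), 8^4)
  expect_identical(pixels(carpet)[82:162, 82:162], matrix(FALSE, 81, 81))

  tri <- makeFractal("sierpinski_triangle", 256, depth = 7)
  expect_equal(sum(pixels(tri)), 3^7 * 4) # 3^depth cells, 2x2 px each
  expect_error(makeFractal("sierpinski_carpet", 128, depth = 5), "infeasible")
  expect_error(makeFractal("line", 32), ">= 64")
})

test_that("generators are pure functions of parameters and seed", {
  a <- makeFractal("random_cantor_dust", 256, depth = 7, seed = 42)
  b <- makeFractal("random_cantor_dust", 256, depth = 7, seed = 42)
  c <- makeFractal("random_cantor_dust", 256, depth = 7, seed = 43)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a), pixels(c)))

  n1 <- makeVesselNetwork(vesselSimParams(seed = 5, polypCount = 2))
  n2 <- makeVesselNetwork(vesselSimParams(seed = 5, polypCount = 2))
  expect_identical(pixels(n1$clean), pixels(n2$clean))
  expect_identical(pixels(n1$noisy), pixels(n2$noisy))

  c1 <- makeCohort(cohortSimParams(seed = 9))
  c2 <- makeCohort(cohortSimParams(seed = 9))
  expect_identical(c1, c2)
})

test_that("branchless parameters give a straight trunk of dimension ~1", {
  net <- makeVesselNetwork(vesselSimParams(branchProb = 0,
                                           angleJitterDeg = 0, seed = 1))
  cols <- unique(which(pixels(net$clean), arr.ind = TRUE)[, 2])
  expect_lte(diff(range(cols)), 3) # one vessel-width vertical trunk
  expect_equal(fd(fractalDimension(skeletonize(net$clean))), 1.0,
               tolerance = 0.1)
})

test_that("polyp-like dilations appear as separated disks on terminal tips", {
  net <- makeVesselNetwork(vesselSimParams(polypCount = 3, seed = 5))
  centers <- maskMetadata(net$clean)$polypCenters
  tips <- maskMetadata(net$clean)$terminalTips
  expect_identical(nrow(centers), 3L)
  # each polyp center is a terminal tip
  for (k in 1:3) {
    d <- sqrt((tips[, 1] - centers[k, 1])^2 + (tips[, 2] - centers[k, 2])^2)
    expect_lt(min(d), 1e-9)
  }
  # the disks are pairwise non-overlapping: the disk-only raster has 3 parts
  diskOnly <- matrix(FALSE, 256, 256)
  for (k in 1:3) for (i in -5:5) for (j in -5:5)
    if (i^2 + j^2 <= 25)
      diskOnly[round(centers[k, 1]) + i, round(centers[k, 2]) + j] <- TRUE
  expect_identical(max(labelComponents(diskOnly)), 3L)
  # and each disk is drawn into the clean mask
  expect_true(all(pixels(net$clean)[round(centers[, 1]) +
                                      256 * (round(centers[, 2]) - 1)]))
})

test_that("noisy render is Otsu-separable around the clean mask", {
  net <- makeVesselNetwork(vesselSimParams(seed = 17, speckleSigma = 0.3))
  img <- net$noisy
  expect_true(all(pixels(img) >= 0 & pixels(img) <= 255))
  mask <- binarizeAngiogram(img)
  inter <- sum(pixels(mask) & pixels(net$clean))
  union <- sum(pixels(mask) | pixels(net$clean))
  expect_gt(inter / union, 0.6) # segmentation recovers most of the network
})

test_that("cohort generator recovers group means and the FD-area correlation", {
  g <- data.frame(group = c("acute", "complex"),
                  cscForm = c("acute", "complex"),
                  cnvType = c("none", "none"), n = c(5000L, 5000L),
                  age_mean = c(52.20, 68.27), age_sd = c(9.52, 10),
                  bcva_mean = c(87.06, 79.61), bcva_sd = c(18.58, 23.32),
                  vpd_mean = NA, vpd_sd = NA, fd_mean = NA, fd_sd = NA,
                  lac_mean = NA, lac_sd = NA, area_mean = NA, area_sd = NA)
  coh <- makeCohort(cohortSimParams(groups = g, seed = 3))
  expect_equal(mean(coh$age_years[coh$csc_form == "acute"]), 52.20,
               tolerance = 0.5)
  expect_equal(mean(coh$age_years[coh$csc_form == "complex"]), 68.27,
               tolerance = 0.5)

  gc <- data.frame(group = c("type1", "pcv"), cscForm = "complex",
                   cnvType = c("type1", "pcv"), n = c(5000L, 5000L),
                   age_mean = 70, age_sd = 10, bcva_mean = 80, bcva_sd = 15,
                   vpd_mean = 0.5, vpd_sd = 0.2, fd_mean = 1.44, fd_sd = 0.12,
                   lac_mean = 2.4, lac_sd = 1.1, area_mean = 2.33,
                   area_sd = 2.06)
  nullCoh <- makeCohort(cohortSimParams(groups = gc, trueCorrFdArea = 0,
                                        seed = 4))
  expect_lt(abs(cor(nullCoh$fd, nullCoh$area_mm2)), 0.05)
  posCoh <- makeCohort(cohortSimParams(groups = gc, trueCorrFdArea = 0.8,
                                       seed = 5))
  expect_equal(cor(posCoh$fd, posCoh$area_mm2), 0.8, tolerance = 0.03)
})
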