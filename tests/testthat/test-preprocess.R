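bimodalImage <- function(lo = 10, hi = 200, n = 32) {
  angiogramImage(matrix(rep(c(lo, hi), each = n * n / 2), n, n), 0.01)
}

test_that("Otsu separates a clean bimodal image and rejects constants", {
  res <- otsuThreshold(bimodalImage())
  expect_gte(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_identical(sum(pixels(res$mask)), 512L)
  expect_error(otsuThreshold(angiogramImage(matrix(42, 32, 32), 0.01)),
               "constant")
})

test_that("Otsu equals exhaustive between-class variance search", {
  set.seed(101)
  for (k in 1:30) {
    v <- sample(0:255, 32 * 32, replace = TRUE)
    if (k %% 3 == 0) # bimodal mixtures too, not only uniform noise
      v <- c(rpois(512, 40), rpois(512, 180))
    img <- angiogramImage(matrix(v, 32, 32), 0.01)
    res <- otsuThreshold(img)
    expect_equal(res$threshold, oracleOtsu(v))
    expect_identical(pixels(res$mask), matrix(v > oracleOtsu(v), 32, 32))
  }
})

test_that("Otsu partition agrees with the EBImage implementation", {
  # thresholds are not comparable (any cut inside an empty histogram gap
  # induces the same partition), so compare the binarized masks
  set.seed(19)
  for (k in 1:10) {
    v <- pmin(c(rpois(512, runif(1, 30, 70)), rpois(512, runif(1, 150, 210))),
              255)
    img <- angiogramImage(matrix(v, 32, 32), 0.01)
    mine <- pixels(otsuThreshold(img)$mask)
    ebT <- EBImage::otsu(EBImage::Image(matrix(v / 255, 32, 32)),
                         range = c(0, 1), levels = 256)
    expect_identical(mine, matrix(v / 255 > ebT, 32, 32))
  }
})

test_that("Otsu threshold maps under intensity scaling into the 16-bit range", {
  set.seed(7)
  v <- sample(0:255, 1024, replace = TRUE)
  img8 <- angiogramImage(matrix(v, 32, 32), 0.01)
  img16 <- angiogramImage(matrix(v * 256, 32, 32), 0.01)
  r8 <- otsuThreshold(img8)
  r16 <- otsuThreshold(img16)
  expect_identical(pixels(r8$mask), pixels(r16$mask))
  expect_equal(r16$threshold, r8$threshold * 256)
})

test_that("preprocessing commutes with mirroring", {
  set.seed(21)
  v <- matrix(c(rpois(512, 30), rpois(512, 150)), 32, 32)
  img <- angiogramImage(v, 0.01)
  flip <- angiogramImage(v[, 32:1], 0.01)
  m1 <- pixels(binarizeAngiogram(img))
  m2 <- pixels(binarizeAngiogram(flip))
  expect_identical(m1, m2[, 32:1])
})

test_that("median despeckle matches the disk-majority oracle", {
  allTrue <- binaryMask(matrix(TRUE, 20, 20))
  expect_true(all(pixels(medianDespeckle(allTrue))))
  speck <- binaryMask(matrix(FALSE, 32, 32))
  speck@pixels[16, 16] <- TRUE
  expect_false(any(pixels(medianDespeckle(speck, 2))))
  set.seed(33)
  for (k in 1:8) {
    m <- randomMask(32, 32, runif(1, 0.3, 0.7))
    got <- pixels(medianDespeckle(binaryMask(m), 2))
    expect_identical(got, oracleMajorityDisk(m, 2))
  }
  expect_error(medianDespeckle(binaryMask(matrix(TRUE, 20, 20)), 11),
               "half the image extent")
})

test_that("small-component removal matches flood-fill survivor sets", {
  m <- matrix(FALSE, 32, 32)
  m[2:4, 2:4] <- TRUE          # 9 px blob
  m[10:14, 10:11] <- TRUE      # 10 px blob
  out <- pixels(removeSmallComponents(binaryMask(m), 10))
  expect_identical(sum(out), 10L)
  expect_true(all(out[10:14, 10:11]))
  expect_false(any(out[2:4, 2:4]))

  empty <- removeSmallComponents(binaryMask(matrix(FALSE, 20, 20)))
  expect_false(any(pixels(empty)))

  set.seed(44)
  for (conn in c(4L, 8L)) for (k in 1:10) {
    m <- randomMask(32, 32, 0.4)
    got <- pixels(removeSmallComponents(binaryMask(m), 10, conn))
    lab <- oracleFloodLabel(m, conn)
    sizes <- tabulate(lab)
    expected <- m & matrix(lab %in% which(sizes >= 10), 32, 32)
    expect_identical(got, expected)
    # surviving component sizes all >= 10 under independent labeling
    survivorSizes <- tabulate(oracleFloodLabel(got, conn))
    expect_true(all(survivorSizes[survivorSizes > 0] >= 10))
  }
})

test_that("small-component removal is idempotent and never adds foreground", {
  set.seed(55)
  for (k in 1:20) {
    m <- binaryMask(randomMask(24, 24, runif(1, 0.2, 0.6)))
    once <- removeSmallComponents(m, 8)
    twice <- removeSmallComponents(once, 8)
    expect_identical(pixels(once), pixels(twice))
    expect_lte(sum(pixels(once)), sum(pixels(m)))
  }
})

test_that("binarize pipeline composes the three steps with provenance", {
  set.seed(66)
  base <- matrix(30, 48, 48)
  base[10:40, 20:26] <- 200          # a thick bar that survives
  base[4, 4] <- 210                  # isolated bright speck
  img <- angiogramImage(base + matrix(rpois(48 * 48, 4), 48, 48), 0.01)
  mask <- binarizeAngiogram(img)
  expect_identical(provenance(mask),
                   c("otsu_threshold", "median_despeckle",
                     "remove_small_components"))
  expect_false(pixels(mask)[4, 4])   # speck despeckled away
  expect_true(any(pixels(mask)[20:30, 22:24]))
  # manual composition gives the identical mask
  manual <- removeSmallComponents(
    medianDespeckle(otsuThreshold(img)$mask, 2), 10, 8)
  expect_identical(pixels(mask), pixels(manual))
  expect_error(binarizeAngiogram(angiogramImage(matrix(5, 32, 32), 0.01)),
               "constant")
})

test_that("binarizing a noisy render recovers the clean vessel fraction", {
  net <- makeVesselNetwork(vesselSimParams(seed = 9, speckleSigma = 0.4))
  mask <- binarizeAngiogram(net$noisy)
  despeckled <- medianDespeckle(otsuThreshold(net$noisy)$mask, 2)
  # component removal never adds to the despeckled mask
  expect_lte(sum(pixels(mask)), sum(pixels(despeckled)))
  expect_gt(sum(pixels(mask)), 0)
  cleanFrac <- mean(pixels(net$clean))
  expect_gt(mean(pixels(mask)), 0.3 * cleanFrac)
  expect_lt(mean(pixels(mask)), 1.7 * cleanFrac)
})
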