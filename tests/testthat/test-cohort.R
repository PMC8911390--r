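# Deterministic fixture encoding the published cohort counts:
# 102 eyes, 40 acute / 62 complex, 37 CNV (all complex; 11 type 1, 26 PCV),
# 20 of 26 PCV eyes with polyp correspondence on OCT-A.
publishedCountsFixture <- function() {
  data.frame(
    eye_id = sprintf("eye%03d", 1:102),
    csc_form = rep(c("acute", "complex"), c(40, 62)),
    cnv_type = c(rep("none", 40), rep("none", 25), rep("type1", 11),
                 rep("pcv", 26)),
    polyps_on_octa = c(rep(NA, 76), rep(TRUE, 20), rep(FALSE, 6)),
    stringsAsFactors = FALSE)
}

test_that("cohort summary reproduces the published count percentages", {
  summ <- summarizeCohort(publishedCountsFixture())
  s <- summ$strata
  getPct <- function(stratum, level)
    s$pct[s$stratum == stratum & s$level == level]
  expect_equal(getPct("cnv_of_all", "cnv"), 36.27)
  expect_equal(getPct("cnv_type_of_cnv", "type1"), 29.73)
  expect_equal(getPct("cnv_type_of_cnv", "pcv"), 70.27)
  expect_equal(roundHalfUp(getPct("csc_form", "acute"), 1), 39.2)
  expect_equal(roundHalfUp(getPct("csc_form", "complex"), 1), 60.8)
  expect_equal(roundHalfUp(getPct("polyp_correspondence_of_pcv", "polyps"), 1),
               76.9)
  expect_equal(getPct("cnv_of_complex", "cnv"), roundHalfUp(100 * 37 / 62, 2))
})

test_that("summary percentages are exact count ratios within each stratum", {
  one <- data.frame(eye_id = "a", csc_form = "acute", cnv_type = "none")
  s <- summarizeCohort(one)$strata
  expect_equal(s$pct[s$stratum == "csc_form" & s$level == "acute"], 100)
  set.seed(2)
  for (k in 1:10) {
    rec <- data.frame(
      eye_id = sprintf("e%d", 1:50),
      csc_form = sample(c("acute", "complex"), 50, replace = TRUE),
      cnv_type = "none", stringsAsFactors = FALSE)
    rec$cnv_type[rec$csc_form == "complex"] <-
      sample(c("none", "type1", "pcv"),
             sum(rec$csc_form == "complex"), replace = TRUE)
    s <- summarizeCohort(rec)$strata
    forms <- s[s$stratum == "csc_form", ]
    expect_equal(sum(forms$pct), 100, tolerance = 0.011)
    expect_equal(forms$pct, roundHalfUp(100 * forms$n / 50, 2))
  }
  expect_error(summarizeCohort(data.frame()), "empty")
  bad <- data.frame(eye_id = "x", csc_form = "acute", cnv_type = "pcv")
  expect_warning(summarizeCohort(bad), "complex")
})

test_that("t-test from raw samples equals the summary-statistic path exactly", {
  set.seed(61)
  for (variant in c("welch", "student")) for (k in 1:5) {
    x <- rnorm(17, 1, 2); y <- rnorm(23, 0.4, 1.1)
    raw <- twoSampleT(x, y, variant)
    summ <- twoSampleT(list(n = 17, mean = mean(x), sd = sd(x)),
                       list(n = 23, mean = mean(y), sd = sd(y)), variant)
    expect_equal(raw@tStatistic, summ@tStatistic, tolerance = 1e-10)
    expect_equal(raw@pValue, summ@pValue, tolerance = 1e-10)
    # and both equal stats::t.test on the raw data
    ref <- stats::t.test(x, y, var.equal = (variant == "student"))
    expect_equal(raw@tStatistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(raw@df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(raw@pValue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("t-test handles identical groups, published summaries, and power", {
  x <- c(1, 2, 3, 4, 5)
  same <- twoSampleT(x, x, "student")
  expect_equal(same@tStatistic, 0)
  expect_equal(pValue(same), 1)

  # published age summaries: acute vs complex, hugely significant
  age <- twoSampleT(list(n = 40, mean = 52.20, sd = 9.52),
                    list(n = 62, mean = 68.27, sd = 10.00))
  ref <- stats::t.test(exactMomentSample(40, 52.20, 9.52, 1),
                       exactMomentSample(62, 68.27, 10.00, 2))
  expect_equal(age@tStatistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(age@df, unname(ref$parameter), tolerance = 1e-9)
  expect_lt(pValue(age), 0.0001)

  set.seed(71)
  big <- twoSampleT(rnorm(10000, 0), rnorm(10000, 1))
  expect_lt(pValue(big), 1e-6)
  expect_error(twoSampleT(list(n = 5, mean = 1, sd = 0),
                          list(n = 5, mean = 2, sd = 1)), "sd > 0")
  expect_error(twoSampleT(1, c(1, 2)), "n >= 2")
})

test_that("Pearson correlation matches cor.test and handles exact lines", {
  x <- c(1.2, 3.1, 4.8, 5.5, 7.9)
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearsonCorr(x, -x)$r, -1.0)
  fx <- c(2.1, 3.4, 1.2, 5.6, 4.4, 6.1, 0.3, 7.7, 2.9, 5.0)
  fy <- c(1.0, 2.9, 0.7, 4.9, 5.1, 5.8, 1.1, 6.2, 2.2, 4.1)
  got <- pearsonCorr(fx, fy)
  ref <- stats::cor.test(fx, fy)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonCorr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonCorr(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("t-test type-I error is calibrated near the nominal 5% level", {
  set.seed(81)
  reps <- 600
  rej <- vapply(seq_len(reps), function(i) {
    pValue(twoSampleT(rnorm(20), rnorm(20))) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.075)
})

test_that("CNV group comparison reports all four metrics and the correlation", {
  gc <- data.frame(group = c("type1", "pcv"), cscForm = "complex",
                   cnvType = c("type1", "pcv"), n = c(30L, 30L),
                   age_mean = 70, age_sd = 10, bcva_mean = 80, bcva_sd = 15,
                   vpd_mean = 0.5, vpd_sd = 0.2, fd_mean = 1.44,
                   fd_sd = 0.12, lac_mean = 2.4, lac_sd = 1.1,
                   area_mean = 2.33, area_sd = 2.06)
  coh <- makeCohort(cohortSimParams(groups = gc, seed = 12))
  rep <- compareCnvGroups(coh)
  expect_identical(rep$comparisons$metric, c("area_mm2", "vpd", "fd", "lac"))
  expect_true(all(rep$comparisons$p_value >= 0 & rep$comparisons$p_value <= 1))
  expect_identical(nrow(rep$table), 4L)
  expect_true(is.finite(rep$correlation$r))

  # power: FD means separated by 3 pooled SDs must be detected
  gc2 <- gc
  gc2$fd_mean <- c(1.44, 1.44 + 3 * 0.12)
  coh2 <- makeCohort(cohortSimParams(groups = gc2, seed = 13))
  rep2 <- compareCnvGroups(coh2)
  expect_lt(rep2$comparisons$p_value[rep2$comparisons$metric == "fd"], 0.01)

  expect_error(compareCnvGroups(coh[coh$cnv_type == "pcv", ]), "both CNV")
})

test_that("identically distributed CNV groups rarely test significant", {
  gc <- data.frame(group = c("type1", "pcv"), cscForm = "complex",
                   cnvType = c("type1", "pcv"), n = c(11L, 26L),
                   age_mean = 70, age_sd = 10, bcva_mean = 80, bcva_sd = 15,
                   vpd_mean = 0.52, vpd_sd = 0.2, fd_mean = 1.44,
                   fd_sd = 0.12, lac_mean = 2.4, lac_sd = 1.1,
                   area_mean = 2.33, area_sd = 2.06)
  allNull <- vapply(1:40, function(s) {
    coh <- makeCohort(cohortSimParams(groups = gc, seed = s))
    all(compareCnvGroups(coh)$comparisons$p_value > 0.05)
  }, logical(1))
  expect_gte(mean(allNull), 0.6) # ~0.95^4 under independence
})
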