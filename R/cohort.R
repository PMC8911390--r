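# Cohort statistics: stratified count summaries with percentages,
# two-sample t-tests (raw or summary input), Pearson correlation, and the
# type 1 CNV vs PCV comparison report.

summaryTriple <- function(x) {
  if (is.list(x)) {
    missing <- setdiff(c("n", "mean", "sd"), names(x))
    if (length(missing))
      stopValidation("summary input needs fields: %s",
                     paste(missing, collapse = ", "))
    if (x$n < 2) stopValidation("each group needs n >= 2")
    if (!is.finite(x$sd) || x$sd <= 0)
      stopValidation("summary input needs sd > 0")
    list(n = x$n, mean = x$mean, sd = x$sd)
  } else {
    x <- x[is.finite(x)]
    if (length(x) < 2) stopValidation("each group needs n >= 2 finite values")
    list(n = length(x), mean = mean(x), sd = stats::sd(x))
  }
}

#' Two-sample t-test from raw samples or summary statistics
#'
#' Accepts either raw numeric vectors or `(n, mean, sd)` summary lists for
#' each group, so published summary tables can be tested directly. The
#' Welch variant (default) uses the Welch-Satterthwaite degrees of freedom;
#' the Student variant pools the variances. P-values are two-sided. Raw
#' input is reduced to its summary triple first, so both input forms give
#' identical results.
#'
#' @param x,y numeric vectors or lists `list(n=, mean=, sd=)`.
#' @param variant "welch" (default) or "student".
#' @param labels length-2 character labels for the groups.
#' @return a [GroupComparison-class].
#' @examples
#' twoSampleT(list(n = 40, mean = 52.20, sd = 9.52),
#'            list(n = 62, mean = 68.27, sd = 10))
#' @export
twoSampleT <- function(x, y, variant = c("welch", "student"),
                       labels = c("x", "y")) {
  variant <- match.arg(variant)
  a <- summaryTriple(x); b <- summaryTriple(y)
  if (variant == "welch") {
    vab <- a$sd^2 / a$n + b$sd^2 / b$n
    if (vab <= 0) stopDegenerate("zero variance in both groups")
    t <- (a$mean - b$mean) / sqrt(vab)
    df <- vab^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 <= 0) stopDegenerate("degenerate pooled variance")
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  new("GroupComparison", groupLabels = labels, n = c(a$n, b$n),
      groupMean = c(a$mean, b$mean), groupSd = c(a$sd, b$sd),
      tStatistic = t, df = df, pValue = p, variant = variant)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation computed from the cross-product formula, with the
#' two-sided p-value from the t transform `t = r sqrt((n-2)/(1-r^2))` on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearsonCorr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopValidation("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopDegenerate("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

requireRecordColumns <- function(records, cols) {
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stopValidation("records are missing columns: %s",
                   paste(missing, collapse = ", "))
}

#' Stratified cohort summary with percentages
#'
#' Counts and percentages per stratum — acute/complex of all eyes, CNV of
#' all and of complex eyes, type 1/PCV of CNV eyes, polyp correspondence of
#' PCV eyes — plus mean and SD of continuous fields per CSCR form and per
#' CNV type. Percentages are rounded half-up to two decimals of the
#' stratum's own denominator. Records with a CNV outside the complex form
#' raise a warning (they contradict the observed cohort structure) but are
#' kept.
#'
#' @param records data.frame of eye-level records with columns `eye_id`,
#'   `csc_form` ("acute"/"complex"), `cnv_type` ("none"/"type1"/"pcv"),
#'   optionally `polyps_on_octa` and continuous fields (`age_years`,
#'   `bcva_letters`, `vpd`, `fd`, `lac`, `area_mm2`).
#' @return list with `strata` (stratum, level, n, denominator, pct) and
#'   `continuous` (grouping, group, variable, n, mean, sd) data.frames.
#' @export
summarizeCohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopDegenerate("empty cohort: nothing to summarize")
  requireRecordColumns(records, c("eye_id", "csc_form", "cnv_type"))
  if (any(records$cnv_type != "none" & records$csc_form != "complex"))
    warning("CNV recorded outside the complex CSCR form")
  pct <- function(k, d) if (d == 0) NA_real_ else roundHalfUp(100 * k / d, 2L)
  nAll <- nrow(records)
  strata <- list()
  addRow <- function(stratum, level, k, d)
    strata[[length(strata) + 1L]] <<- data.frame(
      stratum = stratum, level = level, n = k, denominator = d,
      pct = pct(k, d), stringsAsFactors = FALSE)
  for (lev in c("acute", "complex"))
    addRow("csc_form", lev, sum(records$csc_form == lev), nAll)
  isCnv <- records$cnv_type != "none"
  addRow("cnv_of_all", "cnv", sum(isCnv), nAll)
  nComplex <- sum(records$csc_form == "complex")
  addRow("cnv_of_complex", "cnv", sum(isCnv & records$csc_form == "complex"),
         nComplex)
  for (lev in c("type1", "pcv"))
    addRow("cnv_type_of_cnv", lev, sum(records$cnv_type == lev), sum(isCnv))
  if ("polyps_on_octa" %in% names(records)) {
    pcv <- records$cnv_type == "pcv" & !is.na(records$polyps_on_octa)
    if (any(pcv))
      addRow("polyp_correspondence_of_pcv", "polyps",
             sum(records$polyps_on_octa[pcv]), sum(pcv))
  }
  contVars <- intersect(c("age_years", "bcva_letters", "vpd", "fd", "lac",
                          "area_mm2"), names(records))
  cont <- list()
  for (grouping in c("csc_form", "cnv_type")) {
    for (grp in unique(records[[grouping]])) {
      sel <- records[[grouping]] == grp
      for (v in contVars) {
        vals <- records[[v]][sel]
        vals <- vals[is.finite(vals)]
        if (length(vals) < 2L) next
        cont[[length(cont) + 1L]] <- data.frame(
          grouping = grouping, group = grp, variable = v, n = length(vals),
          mean = mean(vals), sd = stats::sd(vals), stringsAsFactors = FALSE)
      }
    }
  }
  list(strata = do.call(rbind, strata),
       continuous = if (length(cont)) do.call(rbind, cont) else NULL)
}

# Advisory normality screen; never branches the analysis.
normalityAdvisory <- function(x, label) {
  x <- x[is.finite(x)]
  if (length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0) {
    p <- stats::shapiro.test(x)$p.value
    if (p < 0.05)
      message(sprintf(
        "note: '%s' deviates from normality (Shapiro-Wilk p = %.3g)",
        label, p))
  }
  invisible(NULL)
}

#' Compare type 1 CNV and PCV lesion metrics
#'
#' Two-sample t-tests (Welch by default) for lesion area, VPD, FD and LAC
#' between the type 1 CNV and PCV groups, plus the Pearson correlation of
#' FD with lesion area across all CNV eyes — the quantitative comparison
#' layer of the study. A Shapiro-Wilk screen is run per metric and group as
#' an advisory message only.
#'
#' @param records eye-level data.frame as for [summarizeCohort()], with
#'   metric columns `area_mm2`, `vpd`, `fd`, `lac` present for CNV eyes.
#' @param variant t-test variant, "welch" (default) or "student".
#' @param checkNormality emit advisory normality messages.
#' @return list with `comparisons` (one row per metric), `correlation`
#'   (FD vs area: r, p_value, n) and `table` (a publication-shaped
#'   mean +/- SD table with p-values).
#' @export
compareCnvGroups <- function(records, variant = c("welch", "student"),
                             checkNormality = FALSE) {
  variant <- match.arg(variant)
  requireRecordColumns(records, c("cnv_type", "area_mm2", "vpd", "fd", "lac"))
  metrics <- c(area_mm2 = "area_mm2", vpd = "vpd", fd = "fd", lac = "lac")
  g1 <- records[records$cnv_type == "type1", ]
  g2 <- records[records$cnv_type == "pcv", ]
  if (sum(is.finite(g1$fd)) < 2L || sum(is.finite(g2$fd)) < 2L)
    stopDegenerate("both CNV groups need >= 2 eyes with metrics")
  rows <- lapply(names(metrics), function(v) {
    x <- g1[[v]]; y <- g2[[v]]
    if (checkNormality) {
      normalityAdvisory(x, paste0("type1 ", v))
      normalityAdvisory(y, paste0("pcv ", v))
    }
    cmp <- twoSampleT(x, y, variant = variant, labels = c("type1", "pcv"))
    data.frame(metric = v, n_type1 = cmp@n[1], n_pcv = cmp@n[2],
               mean_type1 = cmp@groupMean[1], sd_type1 = cmp@groupSd[1],
               mean_pcv = cmp@groupMean[2], sd_pcv = cmp@groupSd[2],
               t = cmp@tStatistic, df = cmp@df, p_value = cmp@pValue,
               variant = cmp@variant, stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, rows)
  cnv <- records[records$cnv_type %in% c("type1", "pcv"), ]
  correlation <- pearsonCorr(cnv$fd, cnv$area_mm2)
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  table <- data.frame(
    Parameter = c("Area (mm^2)", "VPD (fraction)", "FD", "LAC"),
    `Type 1 CNV` = fmt(comparisons$mean_type1, comparisons$sd_type1),
    PCV = fmt(comparisons$mean_pcv, comparisons$sd_pcv),
    `p Value` = signif(comparisons$p_value, 2),
    check.names = FALSE, stringsAsFactors = FALSE)
  list(comparisons = comparisons, correlation = correlation, table = table)
}
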