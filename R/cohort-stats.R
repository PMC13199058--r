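#' Normality-gated choice of two-group test
#'
#' Applies the Shapiro-Wilk test to each sample: the two-sample t test is
#' used iff both samples are compatible with normality (Shapiro-Wilk
#' p >= `alpha` in both); otherwise the Mann-Whitney U test. Constant
#' samples (degenerate variance, Shapiro-Wilk undefined) route to
#' Mann-Whitney.
#'
#' @param sampleA,sampleB numeric vectors, each of length >= 3.
#' @param alpha normality-gate level (default 0.05).
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
chooseTest <- function(sampleA, sampleB, alpha = 0.05) {
  if (length(sampleA) < 3L || length(sampleB) < 3L)
    stop("each sample must have at least 3 observations for Shapiro-Wilk")
  pvals <- vapply(list(sampleA, sampleB), function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }, numeric(1))
  if (all(pvals >= alpha)) "t_test" else "mann_whitney"
}

#' Two-group comparison of one region's voxel counts
#'
#' Compares a region's per-case counts between the two treatment groups:
#' medians and IQRs (q1-q3, linear interpolation) per group, the test
#' chosen by [chooseTest()], and a two-sided p-value. The Mann-Whitney
#' path uses the exact null distribution when both groups have n <= 8 and
#' the pooled data are tie-free, and the tie-corrected normal approximation
#' with continuity correction otherwise; the t path is Welch's t test.
#'
#' @param cohort `data.frame` of region counts joined with the cohort
#'   table (one row per case).
#' @param region column name of the region to compare.
#' @param groupField column holding the two-level group factor
#'   (default `"group"`).
#' @param alpha normality-gate level passed to [chooseTest()].
#' @return A one-row `data.frame`: region, the two group labels, medians,
#'   quartiles, `test_used`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compareRegion <- function(cohort, region, groupField = "group",
                          alpha = 0.05) {
  if (!region %in% names(cohort)) stop("unknown region column '", region, "'")
  g <- cohort[[groupField]]
  levs <- if (all(unique(g) %in% .groupLevels))
    intersect(.groupLevels, unique(g)) else sort(unique(g))
  if (length(levs) != 2L)
    stop("'", groupField, "' must have exactly two levels, got: ",
         paste(levs, collapse = ", "))
  a <- cohort[[region]][g == levs[1]]
  b <- cohort[[region]][g == levs[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("both groups need >= 3 cases with '", region, "' populated")
  test <- chooseTest(a, b, alpha = alpha)
  if (test == "t_test") {
    ht <- stats::t.test(a, b)
  } else {
    exact <- length(a) <= 8L && length(b) <= 8L &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  }
  qa <- stats::quantile(a, c(.25, .5, .75), type = 7, names = FALSE)
  qb <- stats::quantile(b, c(.25, .5, .75), type = 7, names = FALSE)
  data.frame(region = region,
             group_a = levs[1], group_b = levs[2],
             group_a_median = qa[2], group_a_q1 = qa[1], group_a_q3 = qa[3],
             group_b_median = qb[2], group_b_q1 = qb[1], group_b_q3 = qb[3],
             test_used = test,
             statistic = unname(ht$statistic),
             p_value = ht$p.value,
             n_a = length(a), n_b = length(b),
             stringsAsFactors = FALSE)
}

#' Compare all regions between groups
#'
#' Runs [compareRegion()] over a set of region columns; optionally appends
#' Benjamini-Hochberg adjusted p-values (off by default: the per-region
#' p-values are reported raw).
#'
#' @param cohort region-counts table joined with group labels.
#' @param regions region columns (defaults to the six analysis regions).
#' @param groupField,alpha passed to [compareRegion()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame`, one row per region.
#' @export
compareAllRegions <- function(cohort, regions = .regionCols,
                              groupField = "group", alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- do.call(rbind, lapply(regions, function(r)
    compareRegion(cohort, r, groupField = groupField, alpha = alpha)))
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Chi-squared comparison of a categorical variable between groups
#'
#' Pearson chi-squared (no continuity correction) on the group-by-level
#' contingency table; `"unknown"` levels are dropped by default.
#'
#' @param records cohort `data.frame` (one row per case).
#' @param variable categorical column to compare.
#' @param groupField grouping column (default `"group"`).
#' @param dropUnknown drop the `"unknown"` level before testing
#'   (default `TRUE`).
#' @return A one-row `data.frame` (`variable`, `statistic`, `dof`,
#'   `p_value`) with the tested table in attribute `"table"`.
#' @export
compareCategorical <- function(records, variable, groupField = "group",
                               dropUnknown = TRUE) {
  if (!variable %in% names(records))
    stop("unknown variable '", variable, "'")
  x <- records[[variable]]
  g <- records[[groupField]]
  if (dropUnknown) {
    keep <- x != "unknown" & !is.na(x)
    x <- x[keep]; g <- g[keep]
  }
  tab <- table(g, x)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("'", variable, "' needs at least a 2x2 table after dropping")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("'", variable, "' has a zero marginal row/column")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- data.frame(variable = variable,
                    statistic = unname(ht$statistic),
                    dof = unname(ht$parameter),
                    p_value = ht$p.value,
                    stringsAsFactors = FALSE)
  attr(out, "table") <- tab
  out
}

#' Stratified two-group comparison of one region
#'
#' Filters the cohort to one level of a stratification covariate (e.g.
#' MGMT-unmethylated) and delegates to [compareRegion()], recording the
#' stratum in the result.
#'
#' @param cohort region-counts table joined with covariates.
#' @param region region column to compare.
#' @param stratumField stratification column.
#' @param stratumLevel level of `stratumField` to keep.
#' @param groupField,alpha passed to [compareRegion()].
#' @return A one-row `data.frame` as [compareRegion()], with `stratum_field`
#'   and `stratum_level` columns prepended.
#' @export
subgroupCompare <- function(cohort, region, stratumField, stratumLevel,
                            groupField = "group", alpha = 0.05) {
  if (!stratumField %in% names(cohort))
    stop("unknown stratum field '", stratumField, "'")
  sub <- cohort[cohort[[stratumField]] == stratumLevel, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("stratum level '", stratumLevel, "' is empty")
  counts <- table(factor(sub[[groupField]]))
  empty <- setdiff(unique(cohort[[groupField]]), names(counts)[counts > 0])
  if (length(empty))
    stop("stratum '", stratumLevel, "' has no cases in group(s): ",
         paste(empty, collapse = ", "))
  res <- compareRegion(sub, region, groupField = groupField, alpha = alpha)
  cbind(data.frame(stratum_field = stratumField,
                   stratum_level = stratumLevel,
                   stringsAsFactors = FALSE), res)
}

#' Progression-free survival summary per group
#'
#' Kaplan-Meier median PFS per group (non-progressed cases censored at
#' their recorded follow-up), progression proportion as
#' `100 * events / n` rounded to one decimal, and the log-rank test
#' between groups.
#'
#' @param records cohort `data.frame` with `progressed` and `pfs_months`.
#' @param groupField grouping column (default `"group"`).
#' @return A list: `groups` (`data.frame` with `group`, `n`, `events`,
#'   `median_pfs_months`, `progression_proportion_pct`) and `logrank_p`
#'   (NA when fewer than two groups have data).
#' @export
survivalSummary <- function(records, groupField = "group") {
  g <- records[[groupField]]
  ev <- as.integer(records$progressed)
  t <- records$pfs_months
  if (sum(ev) == 0L) stop("no progression events in the cohort")
  levs <- if (all(unique(g) %in% .groupLevels))
    intersect(.groupLevels, unique(g)) else sort(unique(g))
  rows <- lapply(levs, function(lv) {
    sel <- g == lv
    n <- sum(sel); events <- sum(ev[sel])
    med <- NA_real_
    ok <- sel & !is.na(t)
    if (any(ok)) {
      fit <- survival::survfit(survival::Surv(t[ok], ev[ok]) ~ 1)
      med <- unname(summary(fit)$table["median"])
    }
    data.frame(group = lv, n = n, events = events,
               median_pfs_months = med,
               progression_proportion_pct = round(100 * events / n, 1),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  lrp <- NA_real_
  ok <- !is.na(t)
  if (length(levs) == 2L && all(table(g[ok]) > 0)) {
    # degenerate inputs (e.g. a point mass of events) make the log-rank
    # variance singular; report NA rather than fail
    lrp <- tryCatch({
      sd <- survival::survdiff(
        survival::Surv(t[ok], ev[ok]) ~ factor(g[ok]))
      1 - stats::pchisq(sd$chisq, df = length(sd$n) - 1)
    }, error = function(e) NA_real_)
  }
  list(groups = groups, logrank_p = lrp)
}
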