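test_that("the normality gate routes skewed data to Mann-Whitney and
           near-uniform data to the t test", {
  set.seed(31)
  skewA <- stats::rlnorm(50, 0, 2)
  skewB <- stats::rlnorm(50, 0, 2)
  expect_identical(chooseTest(skewA, skewB), "mann_whitney")
  # exact arithmetic sequences: Shapiro-Wilk comfortably non-significant
  expect_identical(chooseTest(seq(1, 20), seq(2, 40, by = 2)), "t_test")
  expect_identical(chooseTest(rep(3, 10), seq(1, 10)), "mann_whitney")
  expect_error(chooseTest(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("compareRegion reproduces the exact Mann-Whitney p for fully
           separated small samples", {
  df <- data.frame(group = rep(c("proton", "photon"), each = 3),
                   outside_ctv = c(1, 2, 3, 10, 11, 12))
  # alpha = 1 disables the normality gate so the rank path is exercised
  res <- compareRegion(df, "outside_ctv", alpha = 1)
  expect_identical(res$test_used, "mann_whitney")
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$p_value, mwEnumP(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_equal(res$group_a_median, 2)   # proton listed first
  expect_equal(res$group_b_median, 11)
  expect_equal(c(res$group_b_q1, res$group_b_q3), c(10.5, 11.5))
  # these short arithmetic runs look normal, so the default gate picks t
  expect_identical(compareRegion(df, "outside_ctv")$test_used, "t_test")
})

test_that("relabelling the groups swaps the summaries and keeps p", {
  set.seed(41)
  df <- data.frame(g = rep(c("A", "B"), each = 12),
                   v = c(stats::rlnorm(12, 5, 1), stats::rlnorm(12, 6, 1)))
  r1 <- compareRegion(df, "v", groupField = "g")
  df2 <- df
  df2$g <- ifelse(df$g == "A", "B", "A")
  r2 <- compareRegion(df2, "v", groupField = "g")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$group_a_median, r2$group_b_median)
  expect_equal(r1$group_b_median, r2$group_a_median)
})

test_that("identical group multisets give a null result", {
  vals <- c(3, 9, 27, 81, 243)
  df <- data.frame(group = rep(c("proton", "photon"), each = 5),
                   x = c(vals, vals))
  res <- compareRegion(df, "x")
  expect_gt(res$p_value, 0.9)
  expect_equal(res$group_a_median, res$group_b_median)
})

test_that("the rank test is invariant under monotone transforms", {
  set.seed(53)
  a <- stats::rlnorm(15, 2, 1.5); b <- stats::rlnorm(15, 3.5, 1.5)
  df <- data.frame(group = rep(c("proton", "photon"), c(15, 15)),
                   x = c(a, b), y = log(c(a, b)))
  # rank invariance is a property of the Mann-Whitney path, so pin it
  rx <- compareRegion(df, "x", alpha = 1)
  ry <- compareRegion(df, "y", alpha = 1)
  expect_identical(rx$test_used, "mann_whitney")
  expect_equal(rx$p_value, ry$p_value, tolerance = 1e-12)
})

test_that("exact and corrected-normal Mann-Whitney paths agree closely
           for n = 8 + 8 tie-free samples", {
  set.seed(67)
  for (rep in 1:100) {
    repeat {
      x <- round(stats::rnorm(16, 100, 30), 3)
      if (!anyDuplicated(x)) break
    }
    a <- x[1:8]; b <- x[9:16]
    pe <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))$p.value
    pa <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))$p.value
    expect_lte(abs(pe - pa), 0.05)
  }
})

test_that("chi-squared output matches the closed form and handles
           degenerate tables", {
  # proportional rows: independence by construction
  rec <- data.frame(group = rep(c("proton", "photon"), c(20, 40)),
                    v = c(rep(c("yes", "no"), c(10, 10)),
                          rep(c("yes", "no"), c(20, 20))))
  r0 <- compareCategorical(rec, "v")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # diagonal table: hand-computed statistic 20, dof 1
  rec2 <- data.frame(group = rep(c("proton", "photon"), each = 10),
                     v = rep(c("yes", "no"), each = 10))
  r2 <- compareCategorical(rec2, "v")
  expect_equal(r2$statistic, 20, tolerance = 1e-12)
  expect_identical(as.integer(r2$dof), 1L)
  expect_equal(r2$statistic, chisqFormula(attr(r2, "table")),
               tolerance = 1e-12)

  # all-zero column after restricting to unused factor level
  rec3 <- data.frame(group = rep(c("proton", "photon"), each = 5),
                     v = factor(rep(c("a", "b"), 5),
                                levels = c("a", "b", "c")))
  expect_error(compareCategorical(rec3, "v"), "zero marginal")
})

test_that("subgroup comparison filters then delegates, and names empty
           cells", {
  set.seed(71)
  df <- data.frame(group = rep(c("proton", "photon"), each = 10),
                   mgmt = rep(c("methylated", "unmethylated"), 10),
                   outside_ctv = stats::rlnorm(20, 6, 1))
  full <- compareRegion(df, "outside_ctv")
  trivial <- subgroupCompare(cbind(df, all = "all"), "outside_ctv",
                             "all", "all")
  expect_equal(trivial$p_value, full$p_value, tolerance = 1e-12)
  only <- df[df$group == "proton" | df$mgmt == "methylated", ]
  only$mgmt[only$group == "photon"] <- "methylated"
  only$mgmt[only$group == "proton"] <- "unmethylated"
  expect_error(subgroupCompare(only, "outside_ctv", "mgmt",
                               "unmethylated"), "photon")
})

test_that("a stratum-confined effect is detected in the stratum and not
           in its complement", {
  set.seed(83)
  hits <- c(stratum = 0L, complement = 0L)
  nrep <- 60L
  for (r in seq_len(nrep)) {
    tab <- makeCohortTable(cohortSpec(
      nPerGroup = c(proton = 30L, photon = 30L),
      groupEffect = list(proton = c(inside = 1, transition = 1,
                                    outside_ptv = 1),
                         photon = c(inside = 1, transition = 1,
                                    outside_ptv = 1)),
      covariateFreqs = list(
        mgmt = c(methylated = .5, unmethylated = .5),
        tert = c(mutant = .7, nonmutant = .3),
        subtype = c(RTK_II = .5, MES = .5),
        ttf = c(used = .5, not_used = .5)),
      seed = 1000L + r))
    sel <- tab$group == "proton" & tab$mgmt == "unmethylated"
    tab$outside_ctv[sel] <- tab$outside_ctv[sel] * 10
    ps <- subgroupCompare(tab, "outside_ctv", "mgmt",
                          "unmethylated")$p_value
    pc <- subgroupCompare(tab, "outside_ctv", "mgmt",
                          "methylated")$p_value
    hits["stratum"] <- hits["stratum"] + (ps <= 0.05)
    hits["complement"] <- hits["complement"] + (pc <= 0.05)
  }
  expect_gte(hits[["stratum"]] / nrep, 0.9)
  expect_lte(hits[["complement"]] / nrep, 0.2)
})

test_that("survival summaries report KM medians, event proportions and a
           log-rank p", {
  rec <- rbind(recordsFromCounts(94, 79, "proton"),
               recordsFromCounts(50, 40, "photon"))
  s <- survivalSummary(rec)
  expect_equal(s$groups$progression_proportion_pct, c(84.0, 80.0))
  expect_true(is.finite(s$logrank_p))

  # point mass: all progressed at the same time
  pm <- data.frame(group = rep(c("proton", "photon"), each = 5),
                   progressed = TRUE, pfs_months = 7)
  spm <- survivalSummary(pm)
  expect_equal(spm$groups$median_pfs_months, c(7, 7))

  none <- data.frame(group = "proton", progressed = FALSE, pfs_months = 5)
  expect_error(survivalSummary(none), "no progression events")
})

test_that("optional BH adjustment only appends a column", {
  set.seed(97)
  tab <- makeCohortTable(smallCohortSpec(9, c(proton = 12L, photon = 12L)))
  raw <- compareAllRegions(tab)
  adj <- compareAllRegions(tab, adjust = "BH")
  expect_identical(raw$p_value, adj$p_value)
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-12))
})
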