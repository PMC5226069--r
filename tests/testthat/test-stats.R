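test_that("two-group comparisons match closed-form computations", {
  r <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3),
                     "continuous")
  # pooled-variance t on {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)

  same <- compareGroups(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3),
                        "continuous")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # perfectly separated 2x2 table: Pearson chi-squared = n = 20
  cat2 <- compareGroups(rep(c("x", "y"), each = 10),
                        rep(c("A", "B"), each = 10), "categorical")
  expect_equal(cat2$statistic, 20)
  expect_equal(cat2$df, 1)
  # no continuity correction
  tab <- table(rep(c("A", "B"), each = 10), rep(c("x", "y"), times = 10))
  expect_equal(compareGroups(rep(c("x", "y"), times = 10),
                             rep(c("A", "B"), each = 10),
                             "categorical")$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE)$statistic)))
  expect_warning(
    compareGroups(c("x", "x", "y", "x"), c("A", "A", "A", "B"),
                  "categorical"),
    "expected cell")
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(42)
  x <- c(2.1, 3.4, 2.8, 4.0, 3.1)
  y <- c(4.2, 5.1, 4.4, 5.6, 4.9)
  p <- compareGroups(c(x, y), rep(c("A", "B"), each = 5), "continuous")$p
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- mean(replicate(10000, {
    s <- sample(10, 5)
    abs(mean(pooled[s]) - mean(pooled[-s])) >= obs - 1e-12
  }))
  expect_lt(abs(p - perm), 0.02)
})

test_that("ANOVA with Bonferroni follows the multiplication-and-cap rule", {
  y <- c(1, 2, 3, 4, 5, 6); g <- rep(c("A", "B"), each = 3)
  ab <- anovaBonferroni(y, g, m = 10)
  tt <- t.test(y[1:3], y[4:6], var.equal = TRUE)
  expect_equal(ab$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(ab$p, tt$p.value, tolerance = 1e-9)
  expect_equal(ab$p_adj, min(1, ab$p * 10))
  # cap at 1
  set.seed(1)
  yy <- rnorm(30); gg <- rep(c("A", "B", "C"), each = 10)
  ab2 <- anovaBonferroni(yy, gg, m = 10)
  expect_lte(ab2$p_adj, 1)
  expect_equal(min(1, 0.004 * 10), 0.04)
  expect_equal(min(1, 0.2 * 10), 1.0)
  expect_equal(nrow(ab2$posthoc), 3)
  expect_true(all(ab2$posthoc$p_adj >= ab2$posthoc$p))
  expect_error(anovaBonferroni(yy, rep("A", 30)), "two groups")
})

test_that("ICC(A,1) matches the variance-component construction", {
  # identical raters agree perfectly
  ic <- iccTwoWayRandom(cbind(1:10, 1:10, 1:10))
  expect_equal(ic$icc, 1)
  expect_true(ic$ci[1] <= ic$icc && ic$icc <= ic$ci[2])

  # i.i.d. noise: ICC near zero
  set.seed(11)
  ic0 <- iccTwoWayRandom(matrix(rnorm(200), 100, 2))
  expect_lt(abs(ic0$icc), 0.1)

  # subject variance 9, error variance 1, no rater bias: ICC ~ 0.9
  set.seed(12)
  n <- 200
  subj <- rnorm(n, 0, 3)
  ratings <- cbind(subj + rnorm(n), subj + rnorm(n))
  ic9 <- iccTwoWayRandom(ratings)
  expect_lt(abs(ic9$icc - 0.9), 0.05)
  expect_true(ic9$ci[1] <= ic9$icc && ic9$icc <= ic9$ci[2])
  expect_match(ic9$model, "absolute agreement")

  expect_error(iccTwoWayRandom(matrix(rnorm(8), 4, 2)), "5 subjects")
  bad <- matrix(rnorm(20), 10, 2); bad[3, 1] <- NA
  expect_error(iccTwoWayRandom(bad), "missing")
})

test_that("report tables mirror the cohort comparison layout", {
  cfg <- cohortConfig(nPerArm = c(MBT_I = 5L, MBT_II = 5L, RVPA_I = 5L,
                                  RVPA_II = 5L), seed = 2L)
  coh <- generateCohort(cfg, cine = TRUE)
  geo <- cohortGeometry(coh)
  tabs <- buildReportTables(coh$table, geo)
  # volumetric table: 4 metrics x 3 strata
  expect_identical(nrow(tabs$table2), 12L)
  expect_identical(unique(tabs$table2$stratum),
                   c("Total", "Stage I", "Stage II"))
  expect_true(all(c("iedv", "iesv", "isv", "ef_pct") %in%
                    tabs$table2$variable))
  expect_identical(tabs$table2$significant, tabs$table2$p < 0.05)
  # demographic table carries the categorical rows
  expect_true(any(tabs$table1$variable == "tr_grade"))

  # single-group cohort: descriptive columns only
  onlyM <- coh$table[coh$table$group == "MBT", ]
  geoM <- geo[geo$subject_id %in% onlyM$subject_id, ]
  tabsM <- buildReportTables(onlyM, geoM)
  expect_true(all(is.na(tabsM$table2$p)))
  expect_true(all(is.finite(tabsM$table2$mean_1)))

  # missing stage labels: stratified blocks omitted with a warning
  noStage <- coh$table; noStage$stage <- NA
  expect_warning(t1 <- buildReportTables(noStage, geo), "stage")
  expect_identical(unique(t1$table2$stratum), "Total")
})

test_that("under the null the flagged-row rate stays near alpha", {
  set.seed(31)
  nullP <- replicate(300, {
    compareGroups(rnorm(16), rep(c("A", "B"), each = 8), "continuous")$p
  })
  rate <- mean(nullP < 0.05)
  expect_lt(abs(rate - 0.05), 0.035)   # 3 MC sd of Bin(300, 0.05)
})
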