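# Reliability and group-comparison statistics against independent oracles.

test_that("identical rater columns give ICC of exactly 1", {
  x <- cbind(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))
  r <- icc_absolute_agreement(x)
  expect_true(r$icc == 1)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  x <- cbind(c(1, 2, 3, 4), c(1.1, 2.0, 2.9, 4.1))
  r <- icc_absolute_agreement(x)
  expect_equal(r$icc, icc_oracle(x), tolerance = 1e-9)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  expect_true(r$p >= 0 && r$p <= 1)

  set.seed(99)
  y <- matrix(stats::rnorm(60, 10, 3), 20, 3)
  r2 <- icc_absolute_agreement(y)
  expect_equal(r2$icc, icc_oracle(y), tolerance = 1e-9)
})

test_that("absolute agreement penalises a systematic rater offset", {
  set.seed(4)
  a <- stats::rnorm(15, 5, 1)
  r <- icc_absolute_agreement(cbind(a, a + 10 * stats::sd(a)))
  expect_lt(r$icc, 0.9)
  expect_error(icc_absolute_agreement(matrix(3, 4, 2)),
               class = "apexmetry_validation_error")
  expect_error(icc_absolute_agreement(cbind(1:5)),
               class = "apexmetry_validation_error")
})

test_that("shared rater noise degrades ICC monotonically", {
  set.seed(12)
  subjects <- stats::rnorm(12, 0, 1)
  sigmas <- c(0.05, 0.2, 0.5, 1, 2)
  mean_icc <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(r) {
      x <- cbind(subjects + stats::rnorm(12, 0, s),
                 subjects + stats::rnorm(12, 0, s))
      icc_absolute_agreement(x)$icc
    }, 0))
  }, 0)
  expect_equal(stats::cor(sigmas, mean_icc, method = "spearman"), -1)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  eq <- list(c(1, 2, 3), c(1, 2, 3))
  r <- oneway_anova(eq)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  sep <- list(stats::rnorm(10), stats::rnorm(10) + 50, stats::rnorm(10) - 50)
  expect_lt(oneway_anova(sep)$p, 0.001)

  set.seed(21)
  gs <- lapply(1:3, function(i) stats::rnorm(20, i * 0.3, 1))
  r2 <- oneway_anova(gs)
  orc <- anova_oracle(gs)
  expect_equal(r2$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(r2$p, orc$p, tolerance = 1e-9)
  expect_error(oneway_anova(list(1, c(1, 2))),
               class = "apexmetry_validation_error")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(314)
  ps <- vapply(1:2000, function(i) {
    oneway_anova(list(stats::rnorm(10), stats::rnorm(10),
                      stats::rnorm(10)))$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("pooled t-test matches the textbook formula and is antisymmetric", {
  r <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  set.seed(8)
  a <- stats::rnorm(12, 1, 2); b <- stats::rnorm(15, 0.3, 2)
  r1 <- ttest_independent(a, b)
  orc <- ttest_oracle(a, b)
  expect_equal(r1$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(r1$p, orc$p, tolerance = 1e-9)
  r2 <- ttest_independent(b, a)
  expect_equal(r2$statistic, -r1$statistic, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)

  rw <- ttest_independent(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(rw$df, r1$df)))
  expect_error(ttest_independent(c(2, 2, 2), c(2, 2)),
               class = "apexmetry_validation_error")
})

test_that("Fisher's exact test reproduces enumeration on canonical tables", {
  expect_equal(fisher_exact(rbind(c(10, 0), c(0, 10))), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5))), 1, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, 5), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      p <- fisher_exact(tab)
      expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
      expect_equal(fisher_exact(t(tab)), p, tolerance = 1e-12)
      expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-12)
    }
  }
})

test_that("Fisher 2x2 agrees with the reference implementation", {
  set.seed(62)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(4, 8), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-9)
  }
})

test_that("r x c tables use the generalised exact test with a size guard", {
  tab <- rbind(c(3, 12, 5), c(9, 2, 6), c(4, 4, 4))
  expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
               tolerance = 1e-12)
  big <- matrix(50, 3, 3)
  expect_error(fisher_exact(big), class = "apexmetry_capability_error")
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))),
               class = "apexmetry_validation_error")
})

make_records <- function() {
  data.frame(
    specimen_id = sprintf("s%d", 1:6),
    group = rep(c("RPM", "EPM", "EPA"), each = 2),
    d_ac_mm = c(0.2, 0.3, 0.25, 0.35, 0.3, 0.2),
    d_af_mm = c(0.5, 0.7, 0.6, 0.7, 0.66, 0.62),
    ac_af_dist_mm = c(0.3, 0.4, 0.33, 0.39, 0.35, 0.37),
    dist_tip_ac_mm = c(-0.1, 0.1, -0.05, 0.02, -0.2, -0.02),
    dist_tip_af_mm = c(0.2, 0.5, 0.28, 0.41, -0.1, 0.35),
    position_class = c("BETWEEN_AC_AF", "SHORT_OF_AC", "BETWEEN_AC_AF",
                       "SHORT_OF_AC", "BEYOND_AF", "BETWEEN_AC_AF"))
}

test_that("cohort summaries report per-group means, SDs and class counts", {
  recs <- make_records()
  cs <- cohort_summary(recs)
  row <- cs$summary[cs$summary$group == "RPM" &
                      cs$summary$variable == "d_ac_mm", ]
  expect_equal(row$mean, 0.25)
  expect_equal(row$sd, stats::sd(c(0.2, 0.3)))
  expect_equal(unname(cs$counts["EPA", "BEYOND_AF"]), 1L)
  expect_equal(sum(cs$counts), 6L)

  # single record per group: mean echoes the record, SD 0
  one <- recs[c(1, 3, 5), ]
  cs1 <- cohort_summary(one)
  expect_true(all(cs1$summary$sd == 0))
  expect_equal(cs1$summary$mean[cs1$summary$group == "RPM" &
                                  cs1$summary$variable == "d_af_mm"], 0.5)

  # duplicating every record leaves the means unchanged
  cs2 <- cohort_summary(rbind(recs, recs))
  expect_equal(cs2$summary$mean, cs$summary$mean)
  expect_error(cohort_summary(recs[0, ]),
               class = "apexmetry_validation_error")
  expect_error(cohort_summary(recs[, -3]),
               class = "apexmetry_validation_error")
})

test_that("beyond-AF frequency tests produce pairwise and omnibus p-values", {
  recs <- make_records()
  bt <- beyond_af_tests(recs)
  expect_equal(nrow(bt$pairwise), 3)
  expect_true(all(bt$pairwise$p_holm >= bt$pairwise$p - 1e-12))
  expect_true(bt$omnibus_p >= 0 && bt$omnibus_p <= 1)

  # strong imbalance must reach significance
  n <- 60
  strong <- data.frame(
    specimen_id = sprintf("t%d", 1:(2 * n)),
    group = rep(c("EPM", "EPA"), each = n),
    d_ac_mm = 0.27, d_af_mm = 0.64, ac_af_dist_mm = 0.36,
    dist_tip_ac_mm = 0, dist_tip_af_mm = 0.1,
    position_class = c(rep("BETWEEN_AC_AF", n),
                       rep(c("BEYOND_AF", "BETWEEN_AC_AF"), c(n / 2, n / 2))))
  bt2 <- beyond_af_tests(strong)
  expect_lt(bt2$pairwise$p_holm[1], 0.001)
})
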