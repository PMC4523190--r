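# Reliability and group-comparison statistics for cohort measurement tables:
# two-way random-effects intraclass correlation for rater agreement, classical
# one-way ANOVA and pooled t-test for group contrasts of the signed tip
# distances, and Fisher's exact test for position-class frequencies.

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1): single-measurement absolute agreement under a two-way random
#' effects model (subjects and raters both random), the appropriate index
#' when different raters re-measure the same images and absolute values
#' matter. The 95% confidence interval and p-value follow the standard
#' F-based construction (Satterthwaite degrees of freedom for the lower/upper
#' bounds; p from F = MS_rows / MS_error).
#'
#' @param ratings n_subjects x n_raters numeric matrix, no missing cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `p`,
#'   plus the mean squares `msr`, `msc`, `mse` and dimensions.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (!is.numeric(x) || anyNA(x))
    abort("ratings must be a complete numeric matrix",
          "apexmetry_validation_error")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    abort("need at least 2 subjects and 2 raters",
          "apexmetry_validation_error")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ss_total < 1e-300 || abs(denom) < 1e-300)
    abort("ICC undefined: total variance is zero", "apexmetry_validation_error")
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  # McGraw & Wong F-based interval for ICC(A,1)
  if (mse <= 0) {
    ci <- c(icc, icc)   # perfect agreement: interval degenerates
    p <- 0
  } else {
    fj <- msc / mse
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(min(lo, icc), max(hi, icc))
    p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], p = p,
                 msr = msr, msc = msc, mse = mse,
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (95%% CI %.4f-%.4f, p = %.3g), %d x %d\n",
              x$icc, x$ci_low, x$ci_high, x$p, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Classical one-way analysis of variance
#'
#' @param groups List of numeric vectors, one per group, each with >= 2
#'   values.
#' @return List: `statistic` (F), `p`, `df` (between, within).
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    abort("need a list of >= 2 groups", "apexmetry_validation_error")
  if (any(vapply(groups, length, 1L) < 2))
    abort("every group needs >= 2 values", "apexmetry_validation_error")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Independent-samples t-test
#'
#' Two-sided, pooled-variance by default (`welch = TRUE` switches to the
#' Welch unequal-variance form).
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @param welch Use the Welch correction instead of pooling.
#' @return List: `statistic` (t), `p`, `df`.
#' @export
ttest_independent <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    abort("each sample needs >= 2 values", "apexmetry_validation_error")
  fit <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                  error = function(e)
                    abort(paste("t statistic undefined:",
                                conditionMessage(e)),
                          "apexmetry_validation_error"))
  list(statistic = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Fisher's exact test
#'
#' Two-sided exact p-value. For 2x2 tables the full conditional
#' (hypergeometric) distribution given the margins is evaluated directly and
#' the p-value sums the probabilities of all tables no more probable than the
#' observed one. Larger r x c tables use the network-algorithm exact test, or
#' Monte-Carlo estimation when `monte_carlo = TRUE`.
#'
#' @param table Matrix of non-negative integer counts.
#' @param monte_carlo Use Monte-Carlo p estimation for r x c tables too
#'   large to enumerate (2000000 replicates).
#' @return The two-sided exact p-value.
#' @export
fisher_exact <- function(table, monte_carlo = FALSE) {
  x <- as.matrix(table)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    abort("contingency table must hold non-negative integers",
          "apexmetry_validation_error")
  if (all(rowSums(x) == 0) || all(colSums(x) == 0))
    abort("contingency table has no positive margin",
          "apexmetry_validation_error")
  if (nrow(x) == 2 && ncol(x) == 2) {
    a <- x[1, 1]
    r1 <- sum(x[1, ]); r2 <- sum(x[2, ]); c1 <- sum(x[, 1])
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(x[, 2]) == 0) return(1)
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    # relative tolerance mirrors the conventional handling of float ties
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }
  if (monte_carlo)
    return(stats::fisher.test(x, simulate.p.value = TRUE, B = 2e6)$p.value)
  if (sum(x) > 200)
    abort(paste("table total exceeds 200; exact enumeration refused --",
                "set monte_carlo = TRUE for a simulated p-value"),
          "apexmetry_capability_error")
  stats::fisher.test(x)$p.value
}

#' Per-group summary of a cohort measurement table
#'
#' Mean and sample SD (n - 1 denominator) per group for the AC/AF diameters,
#' the AC-AF interval and the signed tip distances, plus a groups x
#' position-class count table.
#'
#' @param records Data frame with the columns written by
#'   [save_measurements()].
#' @return List of class `cohort_summary`: `summary` (long data frame with
#'   group, variable, n, mean, sd) and `counts` (groups x class matrix).
#' @export
cohort_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    abort("records must be a non-empty data frame",
          "apexmetry_validation_error")
  vars <- c("d_ac_mm", "d_af_mm", "ac_af_dist_mm",
            "dist_tip_ac_mm", "dist_tip_af_mm")
  missing <- setdiff(c(vars, "group", "position_class"), names(records))
  if (length(missing))
    abort(paste("records lack columns:", paste(missing, collapse = ", ")),
          "apexmetry_validation_error")
  groups <- unique(records$group)
  if (anyNA(groups))
    abort("every record needs a group label", "apexmetry_validation_error")
  rows <- list()
  for (g in groups) {
    sub <- records[records$group == g, , drop = FALSE]
    if (nrow(sub) == 0)
      abort(sprintf("group %s is empty", g), "apexmetry_validation_error")
    for (v in vars) {
      vals <- sub[[v]]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, n = length(vals), mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0)
    }
  }
  counts <- matrix(0L, length(groups), length(POSITION_CLASSES),
                   dimnames = list(groups, POSITION_CLASSES))
  for (g in groups) {
    tab <- table(factor(records$position_class[records$group == g],
                        levels = POSITION_CLASSES))
    counts[g, ] <- as.integer(tab)
  }
  structure(list(summary = do.call(rbind, rows), counts = counts),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Per-group means (SD):\n")
  print(x$summary, row.names = FALSE)
  cat("\nPosition-class counts:\n")
  print(x$counts)
  invisible(x)
}

#' Exact tests of over-instrumentation frequency between groups
#'
#' Dichotomises the position class into beyond-AF vs not and runs all
#' pairwise 2x2 Fisher exact tests (Holm-adjusted) plus the omnibus
#' groups x {beyond, not-beyond} exact test.
#'
#' @param records Measurement data frame (see [cohort_summary()]).
#' @return List: `pairwise` (data frame with group pair, raw and
#'   Holm-adjusted p), `omnibus_p`.
#' @export
beyond_af_tests <- function(records) {
  cs <- cohort_summary(records)
  beyond <- cs$counts[, "BEYOND_AF"]
  not_beyond <- rowSums(cs$counts) - beyond
  groups <- rownames(cs$counts)
  if (length(groups) < 2)
    abort("need >= 2 groups", "apexmetry_validation_error")
  pairs <- utils::combn(groups, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    tab <- rbind(c(beyond[pr[1]], not_beyond[pr[1]]),
                 c(beyond[pr[2]], not_beyond[pr[2]]))
    fisher_exact(tab)
  })
  omnibus <- cbind(beyond, not_beyond)
  omni_p <- if (sum(omnibus) > 200)
    stats::fisher.test(omnibus, simulate.p.value = TRUE, B = 1e5)$p.value
  else fisher_exact(omnibus)
  list(pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p = p_raw,
                             p_holm = stats::p.adjust(p_raw, "holm")),
       omnibus_p = omni_p)
}
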