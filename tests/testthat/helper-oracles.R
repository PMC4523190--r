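# Independent oracles and fixture builders used across the suite. Every
# oracle recomputes its quantity from first principles (sums of squares,
# factorial enumeration, exhaustive chord search) so the production code
# path is never checked against itself.

# A section in a 1 px = 1 mm frame, convenient for hand geometry.
mm_section <- function(wall_a, wall_b, tip, id = "fixture", ...) {
  annotated_section(id, 1000, wall_a, wall_b, tip, ...)
}

# Exhaustive minimal admissible vertex-pair chord between the two walls of
# a section: every (wall A vertex, wall B vertex) pair whose connecting
# segment crosses neither wall, searched in increasing length order.
brute_force_min_chord <- function(section) {
  sm <- section_mm(section)
  A <- sm$wall_a
  B <- sm$wall_b
  d <- sqrt(outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2)
  ord <- order(d)
  for (k in ord) {
    ij <- arrayInd(k, dim(d))
    a <- A[ij[1], ]; b <- B[ij[2], ]
    if (!apexmetry:::segment_crosses_polyline(a, b, A) &&
        !apexmetry:::segment_crosses_polyline(a, b, B))
      return(list(width = d[k], a = a, b = b))
  }
  stop("no admissible vertex pair")
}

# Two-sided Fisher p for a 2x2 table by full enumeration of the conditional
# distribution, probabilities from log-binomial coefficients.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  pr <- exp(lp)
  p_obs <- pr[support == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# ICC(2,1) from the aov() two-way decomposition (independent route to the
# mean squares) plus the textbook agreement formula.
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Classical one-way ANOVA from explicit sums of squares.
anova_oracle <- function(groups) {
  y <- unlist(groups)
  ni <- lengths(groups)
  grand <- mean(y)
  ssb <- sum(ni * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Pooled-variance two-sample t from the textbook formula.
ttest_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t,
       p = 2 * stats::pt(abs(t), na + nb - 2, lower.tail = FALSE))
}

# Random apex parameter draws mirroring the default cohort conditions,
# with jitter and resolution overridable (used for recovery sweeps).
draw_apex_params <- function(n, seed, jitter = 0, microns_per_pixel = 2) {
  cfg <- default_cohort_config(n_per_group = ceiling(n / 3), seed = seed)
  cfg$contour_jitter_sigma <- jitter
  cfg$microns_per_pixel <- microns_per_pixel
  draws <- sample_cohort_params(cfg)[seq_len(n), ]
  list(config = cfg, draws = draws)
}

measure_quietly <- function(section, ...) {
  suppressWarnings(suppressMessages(measure_section(section, ...)))
}

load_quietly <- function(path) {
  suppressWarnings(suppressMessages(load_annotation(path)))
}
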