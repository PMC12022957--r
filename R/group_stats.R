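#' Case-control statistical layer
#'
#' Group summaries with a normality gate, nonparametric two-group and paired
#' tests, chi-square on 2x2 tables, odds ratios with Woolf confidence
#' intervals, the between-group mean percentage change, Hedges' unbiased
#' standardized mean difference, and the two-sample sample-size plan.
#'
#' The Mann-Whitney U statistic is computed from midranks (so ties count a
#' half each); p-values for the rank tests are delegated to
#' [stats::wilcox.test()] — exact enumeration for small untied samples,
#' normal approximation with tie-corrected variance otherwise.
#'
#' @name group_stats
NULL

#' Summary of one sample with a normality gate
#'
#' Mean, SD (n-1 denominator), t-based 95% CI of the mean, median and
#' quartiles (R's default linear-interpolation convention, type 7), plus a
#' Shapiro-Wilk normality gate. The gate decides how a variable is best
#' presented (mean±SD vs median and IQR); it does not select the test used
#' downstream, which is nonparametric throughout.
#'
#' @param sample Numeric vector, length >= 2.
#' @param alpha Significance level for the normality gate and CI.
#' @return A one-row tibble: `n`, `mean`, `sd`, `ci95_low`, `ci95_high`,
#'   `median`, `iqr_low`, `iqr_high`, `shapiro_w`, `shapiro_p`,
#'   `distribution_normal`.
#' @export
summarize_sample <- function(sample, alpha = 0.05) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  m <- mean(sample)
  s <- stats::sd(sample)
  half <- stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  q <- stats::quantile(sample, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (n >= 3 && s > 0) {
    sw <- stats::shapiro.test(sample)
    w <- unname(sw$statistic); p <- sw$p.value
  } else {
    w <- NA_real_; p <- NA_real_
  }
  tibble::tibble(
    n = n, mean = m, sd = s,
    ci95_low = m - half, ci95_high = m + half,
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    shapiro_w = w, shapiro_p = p,
    distribution_normal = !is.na(p) && p > alpha
  )
}

# Midrank U statistic for x vs y: number of (x_i > y_j) pairs + half-ties.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed from midranks; the two-sided p-value uses exact enumeration
#' when `length(x) * length(y) <= 400` and there are no ties, and the
#' normal approximation with tie-corrected variance (and continuity
#' correction) otherwise.
#'
#' @param x,y Numeric samples (nonempty).
#' @return A list with `U` (for `x`), `p`, and `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = u_statistic(x, y), p = wt$p.value, exact = exact)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Rows are groups (case, control), columns outcome present/absent.
#' Continuity correction is off by default and available as an option. When
#' any expected count is below 5 the result carries a warning flag rather
#' than failing.
#'
#' @param a,b,c,d Counts: case-present, case-absent, control-present,
#'   control-absent.
#' @param correct Apply the Yates continuity correction.
#' @return A list with `statistic`, `p`, `df`, `expected_lt5` (logical).
#' @export
chi2_test <- function(a, b, c, d, correct = FALSE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: chi-square is undefined", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), expected_lt5 = any(expected < 5))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; tied magnitudes get midranks. The p-value
#' is exact when there are at most 25 informative pairs and no ties, and a
#' tie-corrected normal approximation otherwise. When all differences are
#' zero the result is the degenerate (statistic 0, p = 1) outcome, flagged.
#'
#' @param before,after Paired numeric samples of equal length >= 2.
#' @return A list with `statistic` (signed-rank V), `p`, `n_used`,
#'   `degenerate` (logical).
#' @export
wilcoxon_paired <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2)
    stop("need paired samples of equal length >= 2", call. = FALSE)
  diffs <- after - before
  diffs <- diffs[!is.na(diffs)]
  nz <- diffs[diffs != 0]
  if (length(nz) == 0)
    return(list(statistic = 0, p = 1, n_used = 0, degenerate = TRUE))
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(after, before, paired = TRUE, exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(nz), degenerate = FALSE)
}

#' Between-group mean percentage change
#'
#' `100 * (case_mean - control_mean) / case_mean` — the case-group mean is
#' the denominator, the convention used for every "mean change" cell in the
#' comparison tables.
#'
#' @param case_mean,control_mean Group means (case mean nonzero).
#' @return Percent.
#' @export
mean_percentage_change <- function(case_mean, control_mean) {
  if (any(case_mean == 0))
    stop("mean percentage change undefined for a zero case mean", call. = FALSE)
  100 * (case_mean - control_mean) / case_mean
}

#' Odds ratio from a 2x2 table with a Woolf confidence interval
#'
#' `(a*d) / (b*c)` with a 95% CI from the normal approximation on the log
#' odds ratio. Zero cells either raise an error or, under the
#' Haldane-Anscombe policy, add 0.5 to every cell.
#'
#' @inheritParams chi2_test
#' @param zero_cell_policy `"error"` or `"haldane"`.
#' @return A list with `or`, `ci95_low`, `ci95_high`, `corrected` (logical,
#'   TRUE when the Haldane-Anscombe adjustment was applied).
#' @export
odds_ratio <- function(a, b, c, d, zero_cell_policy = c("error", "haldane")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be nonnegative", call. = FALSE)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (zero_cell_policy == "error")
      stop("zero cell in the 2x2 table; use zero_cell_policy = 'haldane'",
           call. = FALSE)
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  list(or = or,
       ci95_low = exp(log(or) - z * se),
       ci95_high = exp(log(or) + z * se),
       corrected = corrected)
}

#' Hedges' unbiased standardized mean difference
#'
#' Cohen's d on the pooled SD, shrunk by the small-sample correction
#' `J = 1 - 3 / (4*(n1+n2) - 9)`. The magnitude label follows the scale
#' small (|g| <= 0.2), medium (around 0.5), large (around 0.8), very large
#' (|g| >= 1.30), with the open intervals split at 0.65 and 1.30.
#'
#' @param mean1,sd1,n1 First group mean, SD and size.
#' @param mean2,sd2,n2 Second group mean, SD and size.
#' @return A list with `g`, `d` (uncorrected), `pooled_sd`, `label`.
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero: effect size undefined", call. = FALSE)
  d <- (mean1 - mean2) / pooled
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- d * j
  label <- effect_label(g)
  list(g = g, d = d, pooled_sd = pooled, label = label)
}

#' Magnitude label for a standardized effect size
#' @param g Effect size (sign ignored).
#' @return `"small"`, `"medium"`, `"large"` or `"very_large"`.
#' @export
effect_label <- function(g) {
  a <- abs(g)
  ifelse(a <= 0.2, "small",
         ifelse(a <= 0.65, "medium",
                ifelse(a < 1.30, "large", "very_large")))
}

#' Two-sample sample-size plan
#'
#' Raw total `N = ((r+1) * (z_alpha_half + z_power)^2 * s^2) / (r * d^2)`,
#' where `r = n1/n2` is the case:control allocation ratio, `s` the pooled SD
#' and `d` the mean difference to detect. Per-group sizes floor the
#' fractional allocation (`n2 = floor(N/(1+r))`, `n1 = floor(r*N/(1+r))`);
#' the attrition revision rounds up: `n_revised = ceiling(n_total / (1 -
#' attrition))`.
#'
#' @param z_alpha_half Normal deviate at the two-sided significance level
#'   (1.96 for 5%).
#' @param z_power Normal deviate at the target power (1.28 for 90%).
#' @param r Allocation ratio n1/n2 (1 for 1:1).
#' @param s Pooled SD of the outcome.
#' @param d Mean difference to detect (nonzero), same units as `s`.
#' @param attrition Anticipated fraction of lost data, in \[0, 1).
#' @return A list with `raw_n`, `n_case`, `n_control`, `n_per_group` (when
#'   `r = 1`), `n_total`, `n_revised`, and the inputs.
#' @export
sample_size <- function(z_alpha_half, z_power, r = 1, s, d, attrition = 0) {
  if (d == 0) stop("d = 0 implies an infinite sample size", call. = FALSE)
  if (s <= 0) stop("s must be positive", call. = FALSE)
  if (attrition < 0 || attrition >= 1)
    stop("attrition must be in [0, 1)", call. = FALSE)
  raw_n <- ((r + 1) * (z_alpha_half + z_power)^2 * s^2) / (r * d^2)
  n_control <- floor(raw_n / (1 + r))
  n_case <- floor(r * raw_n / (1 + r))
  n_total <- n_case + n_control
  n_revised <- ceiling(n_total / (1 - attrition))
  list(z_alpha_half = z_alpha_half, z_power = z_power, r = r, s = s, d = d,
       attrition = attrition, raw_n = raw_n,
       n_case = n_case, n_control = n_control,
       n_per_group = if (r == 1) n_case else NA_integer_,
       n_total = n_total, n_revised = n_revised)
}
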