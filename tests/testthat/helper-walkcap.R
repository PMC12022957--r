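# Shared fixtures and independent oracles.

# A small hand-built valid cohort data frame (built in code, no files).
make_cohort_df <- function(n_case = 3, n_control = 3) {
  n <- n_case + n_control
  sex <- rep(c(0, 1), length.out = n)
  tibble::tibble(
    id = sprintf("p%02d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    sex = sex,
    age = seq(30, 50, length.out = n),
    height = seq(1.60, 1.85, length.out = n),
    weight = seq(60, 95, length.out = n),
    bmi = seq(60, 95, length.out = n) / seq(1.60, 1.85, length.out = n)^2,
    parity = ifelse(sex == 1, 2, NA_real_),
    pack_years = rep(c(0, 10), length.out = n),
    voorrips_daily = rep(1.5, n),
    voorrips_sport = rep(0.5, n),
    voorrips_leisure = rep(0.5, n),
    schooling_level = rep(c("low", "high"), length.out = n),
    socioeconomic_level = rep(c("favorable", "unfavorable"), length.out = n),
    distance_m = seq(600, 720, length.out = n),
    stops = rep(0, n),
    hr_rest = seq(60, 75, length.out = n),
    hr_end = seq(120, 160, length.out = n),
    spo2_rest = rep(98, n),
    spo2_end = rep(97.5, n),
    sbp_rest = rep(118, n),
    sbp_end = rep(145, n),
    dbp_rest = rep(75, n),
    dbp_end = rep(78, n),
    dyspnea_rest = rep(0, n),
    dyspnea_end = rep(2, n)
  )
}

# Brute-force Mann-Whitney U: pairwise count with half-ties.
brute_force_u <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s
}

# Exhaustive signed-rank oracle: enumerate every sign assignment of the
# |difference| ranks and return the two-sided exact p for the observed V.
brute_force_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(statistic = v_obs, p = min(p, 1))
}
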