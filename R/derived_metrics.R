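#' Per-participant derived metrics
#'
#' Scalar transformations of raw walk-test measurements into the standardized
#' quantities the analysis compares: percent of predicted distance, walk work,
#' rest-to-end percentage deltas, oxygen-saturation drop, heart rate as a
#' percent of the maximal predicted value, fitness-age delta and the
#' physiological cost index.
#'
#' @name derived_metrics
NULL

#' Distance as a percent of the predicted value
#' @param measured Measured 6MWD in meters.
#' @param predicted Predicted 6MWD in meters (must be positive).
#' @return Percent (100 when measured equals predicted).
#' @export
percent_predicted <- function(measured, predicted) {
  if (any(predicted <= 0)) stop("predicted must be positive", call. = FALSE)
  100 * measured / predicted
}

#' Six-minute walk work
#'
#' The product of walk distance and body weight (m·kg), a load-adjusted
#' capacity index.
#'
#' @param distance Distance in meters (>= 0).
#' @param weight Weight in kg (> 0).
#' @return Walk work in m·kg.
#' @export
walk_work <- function(distance, weight) {
  if (any(distance < 0)) stop("distance must be nonnegative", call. = FALSE)
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  distance * weight
}

#' Rest-to-end percentage change
#'
#' `100 * (end - rest) / rest`. Undefined when the rest value is zero —
#' which is why no delta is computed for dyspnea (rest dyspnea is 0 in
#' healthy sitting participants); the absolute end value is reported instead.
#'
#' @param end Value at the end of the walk.
#' @param rest Value at rest (must be nonzero).
#' @return Percent change.
#' @export
delta_percent <- function(end, rest) {
  if (any(rest == 0))
    stop("delta is undefined when the rest value is 0", call. = FALSE)
  100 * (end - rest) / rest
}

#' Oxygen saturation drop over the walk
#'
#' Returns `rest - end` in percentage points, oriented so that a positive
#' value is a decline (the desaturation direction). The signed `end - rest`
#' change is reported alongside in [derive_metrics()] for table parity.
#'
#' @param rest,end SpO2 at rest and end, percent in \[50, 100\].
#' @return Drop in percentage points (positive = desaturation).
#' @export
spo2_drop <- function(rest, end) {
  stopifnot(all(rest >= 50 & rest <= 100), all(end >= 50 & end <= 100))
  rest - end
}

#' Heart rate as a percent of the maximal predicted heart rate
#' @param hr Heart rate in bpm (> 0).
#' @param age Age in years.
#' @return Percent of MPHR (see [mphr()]).
#' @export
hr_pct_mphr <- function(hr, age) {
  if (any(hr <= 0)) stop("heart rate must be positive", call. = FALSE)
  m <- mphr(age)
  if (any(m <= 0)) stop("MPHR is nonpositive at this age", call. = FALSE)
  100 * hr / m
}

#' Fitness-age delta
#'
#' Chronological minus ECRMC age, in years; negative values indicate
#' accelerated functional aging.
#'
#' @param chronological Chronological age in years.
#' @param ecrmc ECRMC (fitness) age in years.
#' @return Delta age in years.
#' @export
delta_age <- function(chronological, ecrmc) {
  chronological - ecrmc
}

#' Physiological cost index
#'
#' The heart-rate rise over the walk divided by walking speed in m/min,
#' giving beats per meter. Healthy adults typically fall around 0.23-0.42
#' beats/m.
#'
#' @param hr_end,hr_rest End and rest heart rates in bpm.
#' @param distance Distance walked in 6 minutes, meters (> 0).
#' @return Beats per meter.
#' @export
physiological_cost_index <- function(hr_end, hr_rest, distance) {
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  (hr_end - hr_rest) / (distance / 6)
}

#' Derive all per-participant metrics for a cohort
#'
#' Applies the reference equations and the scalar metrics above to every
#' record. ECRMC ages outside \[0, 120\] years are kept as computed but
#' flagged in `ecrmc_out_of_range` (reference equations can extrapolate
#' beyond a plausible lifespan for extreme walk distances).
#'
#' @param cohort A `walkcap_cohort`.
#' @param coef Coefficient set, see [default_coefficients()].
#' @return A tibble, one row per participant: identifiers, the reference
#'   prediction, and all derived metrics.
#' @export
derive_metrics <- function(cohort, coef = default_coefficients()) {
  stopifnot(inherits(cohort, "walkcap_cohort"))
  r <- cohort$records
  pred <- reference_prediction(r$sex, r$age, r$weight, r$height, r$bmi, coef)
  ecrmc <- ecrmc_age(r$sex, r$age, r$weight, r$height, r$distance_m, coef)
  tibble::tibble(
    id = r$id,
    group = r$group,
    equation_branch = pred$equation_branch,
    predicted_6mwd_m = pred$predicted_6mwd_m,
    lln_6mwd_m = pred$lln_6mwd_m,
    pct_predicted_6mwd = percent_predicted(r$distance_m, pred$predicted_6mwd_m),
    walk_work_m_kg = walk_work(r$distance_m, r$weight),
    mphr_bpm = mphr(r$age, coef),
    hr_rest_pct_mphr = hr_pct_mphr(r$hr_rest, r$age),
    hr_end_pct_mphr = hr_pct_mphr(r$hr_end, r$age),
    delta_hr_pct = delta_percent(r$hr_end, r$hr_rest),
    delta_sbp_pct = delta_percent(r$sbp_end, r$sbp_rest),
    delta_dbp_pct = delta_percent(r$dbp_end, r$dbp_rest),
    delta_spo2_pct = delta_percent(r$spo2_end, r$spo2_rest),
    spo2_drop_points = spo2_drop(r$spo2_rest, r$spo2_end),
    spo2_change_points = r$spo2_end - r$spo2_rest,
    ecrmc_age_years = ecrmc,
    ecrmc_out_of_range = ecrmc < 0 | ecrmc > 120,
    delta_age_years = delta_age(r$age, ecrmc),
    pci_beats_per_m = physiological_cost_index(r$hr_end, r$hr_rest, r$distance_m)
  )
}
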