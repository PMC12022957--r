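#' Threshold classification of signs and statuses
#'
#' Pure threshold rules turning measurements and derived metrics into the
#' categorical statuses and exercise-intolerance flags the case-control
#' comparison counts. Every threshold is applied exactly as defined —
#' strict or inclusive as stated — and the boundary behavior is pinned by
#' tests.
#'
#' @name classification
NULL

#' Abnormal walk distance
#'
#' True when the measured distance falls strictly below the lower limit of
#' normal.
#'
#' @param measured Measured 6MWD in meters (> 0).
#' @param lln Lower limit of normal in meters (> 0).
#' @return Logical.
#' @export
flag_abnormal_6mwd <- function(measured, lln) {
  stopifnot(all(measured > 0), all(lln > 0))
  measured < lln
}

#' Chronotropic insufficiency
#'
#' End-of-walk heart rate strictly below 60% of the maximal predicted heart
#' rate: the heart failed to accelerate adequately with exercise.
#'
#' @param hr_end_pct_mphr End HR as percent of MPHR (> 0).
#' @return Logical.
#' @export
flag_chronotropic_insufficiency <- function(hr_end_pct_mphr) {
  stopifnot(all(hr_end_pct_mphr > 0))
  hr_end_pct_mphr < 60
}

#' Clinically significant desaturation
#'
#' SpO2 drop of strictly more than 5 percentage points over the walk.
#'
#' @param drop_points Drop in points, oriented positive = decline
#'   (see [spo2_drop()]).
#' @return Logical.
#' @export
flag_desaturation <- function(drop_points) {
  drop_points > 5
}

#' High end-of-walk dyspnea
#'
#' Visual-analog dyspnea strictly above 5 out of 10 at the end of the walk.
#'
#' @param dyspnea_end VAS score in \[0, 10\].
#' @return Logical.
#' @export
flag_high_dyspnea <- function(dyspnea_end) {
  stopifnot(all(dyspnea_end >= 0 & dyspnea_end <= 10))
  dyspnea_end > 5
}

#' Corpulence status from BMI
#'
#' Half-open bins partitioning the BMI axis: underweight below 18.5, normal
#' in \[18.5, 25), overweight in \[25, 30), obese at 30 and above.
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @return Character vector of `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"`.
#' @export
classify_corpulence <- function(bmi) {
  stopifnot(all(bmi > 0))
  as.character(cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
                   labels = c("underweight", "normal", "overweight", "obese"),
                   right = FALSE))
}

#' Sedentary status from the Voorrips total score
#'
#' Total physical-activity score strictly below 9.42 classifies a
#' participant sedentary; 9.42 and above is active.
#'
#' @param voorrips_total Total Voorrips score (>= 0).
#' @return Logical (TRUE = sedentary).
#' @export
classify_sedentary <- function(voorrips_total) {
  stopifnot(all(voorrips_total >= 0))
  voorrips_total < 9.42
}

#' Smoker status from pack-years
#'
#' Five pack-years or more classifies a participant as a smoker (inclusive
#' boundary).
#'
#' @param pack_years Pack-years (>= 0).
#' @return Logical (TRUE = smoker).
#' @export
classify_smoker <- function(pack_years) {
  stopifnot(all(pack_years >= 0))
  pack_years >= 5
}

#' High parity (women only)
#'
#' Parity strictly greater than two is high, relative to a national
#' fertility rate of about two children per woman. For men the status is not
#' applicable and `NA` is returned, never `FALSE`.
#'
#' @param parity Integer count of children (>= 0), `NA` for men.
#' @return Logical, `NA` where parity is absent.
#' @export
classify_high_parity <- function(parity) {
  stopifnot(all(is.na(parity) | (parity >= 0 & parity == round(parity))))
  ifelse(is.na(parity), NA, parity > 2)
}

#' Classify signs and statuses for a whole cohort
#'
#' Combines the intolerance flags (abnormal distance, stopping, high
#' dyspnea, desaturation, chronotropic insufficiency) and the categorical
#' statuses (corpulence, sedentary, smoker, high parity) for every
#' participant. Each flag is a pure function of the record and its derived
#' metrics.
#'
#' @param cohort A `walkcap_cohort`.
#' @param metrics Output of [derive_metrics()] for the same cohort; computed
#'   when not supplied.
#' @return A tibble, one row per participant.
#' @export
classify_signs <- function(cohort, metrics = derive_metrics(cohort)) {
  r <- cohort$records
  stopifnot(identical(r$id, metrics$id))
  tibble::tibble(
    id = r$id,
    group = r$group,
    abnormal_6mwd = flag_abnormal_6mwd(r$distance_m, metrics$lln_6mwd_m),
    stopped_during_walk = r$stops > 0,
    high_dyspnea_end = flag_high_dyspnea(r$dyspnea_end),
    desaturation = flag_desaturation(metrics$spo2_drop_points),
    chronotropic_insufficiency =
      flag_chronotropic_insufficiency(metrics$hr_end_pct_mphr),
    corpulence = classify_corpulence(r$bmi),
    sedentary = classify_sedentary(
      r$voorrips_daily + r$voorrips_sport + r$voorrips_leisure),
    smoker = classify_smoker(r$pack_years),
    high_parity = classify_high_parity(r$parity)
  )
}
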