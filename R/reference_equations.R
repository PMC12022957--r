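#' Reference equations for the six-minute walk test
#'
#' Age-branched North African reference equations: predicted six-minute walk
#' distance (6MWD), its lower limit of normal (LLN), the estimated
#' cardiorespiratory-and-muscular-chain (ECRMC) "fitness" age, and the maximal
#' predicted heart rate (MPHR). All equations are linear in their inputs and
#' branch once, on age, at the 40-year boundary. Age exactly 40 is assigned to
#' the 40-plus branch throughout, so prediction and fitness age use the same
#' branch for any one participant.
#'
#' Sex is coded 0 = man, 1 = woman, the convention of the source equations.
#'
#' @name reference_equations
NULL

#' Default coefficient set for the reference equations
#'
#' Returns the registry of coefficients behind [predicted_6mwd()],
#' [lln_6mwd()], [ecrmc_age()] and [mphr()]. Users may supply a modified copy
#' (e.g. equations normed on another population) to the vectorised wrappers;
#' every coefficient must then be named.
#'
#' @return A named list with components `pred_under40`, `pred_40plus`,
#'   `ecrmc_under40`, `ecrmc_40plus` (each a named numeric vector of linear
#'   coefficients), `lln_offset` (named numeric, `under40` / `forty_plus`) and
#'   `mphr` (intercept and age slope).
#' @export
#' @examples
#' default_coefficients()$pred_40plus
default_coefficients <- function() {
  list(
    pred_under40 = c(intercept = 800.05, sex = -64.71, bmi = -10.23,
                     age = -1.63, weight = 2.05),
    pred_40plus  = c(intercept = 720.50, sex = -160.27, age = -5.14,
                     weight = -2.23, height = 271.98),
    ecrmc_under40 = c(intercept = 184.25, distance = -0.36, height = 44.39,
                      sex = -13.87),
    ecrmc_40plus  = c(intercept = 140.17, distance = -0.19, sex = -31.18,
                      weight = -0.43, height = 52.91),
    lln_offset = c(under40 = 74.31, forty_plus = 89),
    mphr = c(intercept = 208, age = -0.7)
  )
}

check_coefficients <- function(coef) {
  ref <- default_coefficients()
  for (nm in names(ref)) {
    if (is.null(coef[[nm]]) || !all(names(ref[[nm]]) %in% names(coef[[nm]])))
      stop("coefficient set is missing entries for '", nm, "'", call. = FALSE)
  }
  invisible(coef)
}

#' Which equation branch applies at a given age
#'
#' @param age Age in years.
#' @return `"under40"` for age < 40, `"forty_plus"` for age >= 40.
#' @export
equation_branch <- function(age) {
  ifelse(age < 40, "under40", "forty_plus")
}

#' Predicted six-minute walk distance
#'
#' For age < 40:
#' `800.05 - 64.71*sex - 10.23*bmi - 1.63*age + 2.05*weight`;
#' for age >= 40:
#' `720.50 - 160.27*sex - 5.14*age - 2.23*weight + 271.98*height`.
#' Height is in meters; sex is 0 (man) / 1 (woman).
#'
#' @param sex 0 = man, 1 = woman.
#' @param age Age in years.
#' @param weight Weight in kg.
#' @param height Height in meters.
#' @param bmi Body mass index in kg/m^2; defaults to `weight / height^2`.
#' @param coef Coefficient set, see [default_coefficients()].
#' @return Predicted 6MWD in meters (vectorised).
#' @export
#' @examples
#' predicted_6mwd(sex = 0, age = 30, weight = 75, height = 1.732, bmi = 25)
predicted_6mwd <- function(sex, age, weight, height, bmi = weight / height^2,
                           coef = default_coefficients()) {
  check_coefficients(coef)
  stopifnot(all(sex %in% c(0, 1)))
  if (any(weight <= 0) || any(height <= 0) || any(bmi <= 0))
    stop("anthropometric inputs must be positive", call. = FALSE)
  u <- coef$pred_under40
  f <- coef$pred_40plus
  under <- u[["intercept"]] + u[["sex"]] * sex + u[["bmi"]] * bmi +
    u[["age"]] * age + u[["weight"]] * weight
  over <- f[["intercept"]] + f[["sex"]] * sex + f[["age"]] * age +
    f[["weight"]] * weight + f[["height"]] * height
  ifelse(age < 40, under, over)
}

#' Lower limit of normal for the six-minute walk distance
#'
#' Subtracts the reference-population offset from the predicted distance:
#' 74.31 m below 40 years of age, 89 m at 40 and above. Distances under the
#' LLN are classified abnormal (see [flag_abnormal_6mwd()]).
#'
#' @param predicted Predicted 6MWD in meters (must be positive).
#' @param age Age in years (selects the offset).
#' @inheritParams predicted_6mwd
#' @return LLN in meters.
#' @export
lln_6mwd <- function(predicted, age, coef = default_coefficients()) {
  check_coefficients(coef)
  if (any(predicted <= 0)) stop("predicted distance must be positive", call. = FALSE)
  off <- coef$lln_offset
  predicted - ifelse(age < 40, off[["under40"]], off[["forty_plus"]])
}

#' Estimated cardiorespiratory-and-muscular-chain (fitness) age
#'
#' For age < 40:
#' `184.25 - 0.36*6MWD + 44.39*height - 13.87*sex`;
#' for age >= 40:
#' `140.17 - 0.19*6MWD - 31.18*sex - 0.43*weight + 52.91*height`.
#' The result is a "fitness age" in years; values above the chronological age
#' indicate accelerated functional aging. The equations can produce values
#' outside a plausible human lifespan for very long or very short walks;
#' these are returned unchanged (callers may flag them, see
#' [derive_metrics()]).
#'
#' @param measured_6mwd Measured walk distance in meters (must be positive).
#' @inheritParams predicted_6mwd
#' @return ECRMC age in years (may be negative).
#' @export
#' @examples
#' ecrmc_age(sex = 0, age = 42, weight = 82, height = 1.71, measured_6mwd = 641)
ecrmc_age <- function(sex, age, weight, height, measured_6mwd,
                      coef = default_coefficients()) {
  check_coefficients(coef)
  stopifnot(all(sex %in% c(0, 1)))
  if (any(measured_6mwd <= 0)) stop("measured distance must be positive", call. = FALSE)
  u <- coef$ecrmc_under40
  f <- coef$ecrmc_40plus
  under <- u[["intercept"]] + u[["distance"]] * measured_6mwd +
    u[["height"]] * height + u[["sex"]] * sex
  over <- f[["intercept"]] + f[["distance"]] * measured_6mwd +
    f[["sex"]] * sex + f[["weight"]] * weight + f[["height"]] * height
  ifelse(age < 40, under, over)
}

#' Maximal predicted heart rate
#'
#' `208 - 0.7 * age`, in beats per minute.
#'
#' @param age Age in years (must be positive).
#' @inheritParams predicted_6mwd
#' @return MPHR in bpm.
#' @export
mphr <- function(age, coef = default_coefficients()) {
  check_coefficients(coef)
  if (any(age < 0)) stop("age must be nonnegative", call. = FALSE)
  coef$mphr[["intercept"]] + coef$mphr[["age"]] * age
}

#' Full reference prediction for one or more participants
#'
#' Convenience wrapper combining [predicted_6mwd()] and [lln_6mwd()].
#'
#' @inheritParams predicted_6mwd
#' @return A tibble with columns `predicted_6mwd_m`, `lln_6mwd_m`,
#'   `equation_branch`.
#' @export
reference_prediction <- function(sex, age, weight, height,
                                 bmi = weight / height^2,
                                 coef = default_coefficients()) {
  pred <- predicted_6mwd(sex, age, weight, height, bmi, coef)
  tibble::tibble(
    predicted_6mwd_m = pred,
    lln_6mwd_m = lln_6mwd(pred, age, coef),
    equation_branch = equation_branch(age)
  )
}
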