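test_that("a fixed spec and seed reproduce the cohort bit for bit", {
  spec <- calibration_preset(seed = 17)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$records, c2$records)
  # and the written CSVs are byte-identical
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draws
  c3 <- generate_cohort(calibration_preset(seed = 18))
  expect_false(identical(c1$records$distance_m, c3$records$distance_m))
})

test_that("the calibration preset encodes the study composition", {
  preset <- calibration_preset()
  expect_equal(preset$case$n, 26)
  expect_equal(preset$control$n, 28)
  expect_equal(round(preset$case$n * preset$case$sex_fraction_women), 11)
  expect_equal(round(preset$control$n * preset$control$sex_fraction_women), 13)
  expect_equal(preset$case$distance$mean, 641)
  expect_equal(preset$control$distance$mean, 702)
  expect_equal(preset$case$hr_end$mean, 127)
  expect_equal(preset$control$hr_end$mean, 153)
  expect_silent(walkcap:::validate_group_spec(preset$case))
})

test_that("sample moments converge to the spec at large n", {
  preset <- calibration_preset(seed = 5)
  preset$case$n <- 10000
  preset$control$n <- 2   # keep the run cheap; only the case group is checked
  coh <- generate_cohort(preset)
  r <- coh$records[coh$records$group == "case", ]
  # variables whose truncation bounds are several SDs out
  checks <- list(
    age = r$age, height = r$height, distance = r$distance_m,
    hr_rest = r$hr_rest, hr_end = r$hr_end,
    sbp_rest = r$sbp_rest, sbp_end = r$sbp_end,
    dbp_rest = r$dbp_rest, dbp_end = r$dbp_end
  )
  for (nm in names(checks)) {
    spec <- preset$case[[nm]]
    expect_lt(abs(mean(checks[[nm]]) - spec$mean) / spec$mean, 0.02,
              label = paste("mean of", nm))
    expect_lt(abs(sd(checks[[nm]]) - spec$sd) / spec$sd, 0.05,
              label = paste("sd of", nm))
  }
  # Bernoulli traits land inside binomial 99% bands
  for (trait in list(
    c(sum(r$pack_years >= 5), 10 / 26),
    c(sum(r$schooling_level == "low"), 8 / 26),
    c(sum(r$socioeconomic_level == "unfavorable"), 9 / 26))) {
    band <- qbinom(c(0.005, 0.995), 10000, trait[2])
    expect_true(trait[1] >= band[1] && trait[1] <= band[2])
  }
  # the copula induces the requested distance-HR correlation
  expect_equal(cor(r$distance_m, r$hr_end), 0.4, tolerance = 0.05)
})

test_that("degenerate and infeasible specs behave as declared", {
  # sd 0 yields a constant column
  preset <- calibration_preset(seed = 2)
  preset$case$hr_rest <- mv(70, 0, 35, 130)
  coh <- generate_cohort(preset)
  expect_equal(unique(coh$records$hr_rest[coh$records$group == "case"]), 70)
  # mean outside the truncation bounds is rejected at spec time
  expect_error(mv(150, 5, 0, 100), "infeasible truncation")
  expect_error(mv(50, -1, 0, 100), "nonnegative")
  expect_error(mv(50, 5, 100, 0), "min < max")
  expect_error(
    group_spec(n = 5, sex_fraction_women = 1.4, age = mv(40, 5, 18, 90),
               height = mv(1.7, 0.1, 1.2, 2.2), weight = mv(80, 10, 40, 180),
               distance = mv(650, 50, 200, 1100), hr_rest = mv(70, 8, 35, 130),
               hr_end = mv(140, 20, 45, 210), spo2_rest = mv(98, 1, 85, 100),
               spo2_end = mv(98, 1, 85, 100), sbp_rest = mv(120, 10, 70, 230),
               sbp_end = mv(140, 15, 70, 260), dbp_rest = mv(75, 10, 35, 140),
               dbp_end = mv(78, 10, 35, 140), dyspnea_end = mv(1.5, 1, 0, 10),
               voorrips_daily = mv(1.8, 0.5, 0, 20),
               voorrips_sport = mv(1, 2, 0, 30),
               voorrips_leisure = mv(0.5, 1, 0, 30),
               parity = mv(2, 1, 0, 12), smoker_prob = 0.3,
               low_schooling_prob = 0.2, unfavorable_ses_prob = 0.2),
    "probabilities")
})

test_that("generated cohorts always pass validation with an empty exclusion log", {
  for (seed in c(1, 23, 456)) {
    coh <- generate_cohort(calibration_preset(seed = seed))
    expect_equal(nrow(coh$records), 54)
    expect_equal(nrow(coh$exclusion_log), 0)
    expect_true(all(coh$records$spo2_rest <= 100))
    expect_true(all(coh$records$dyspnea_end >= 0 & coh$records$dyspnea_end <= 10))
    expect_true(all(coh$records$distance_m >= 200))
    expect_true(all(is.na(coh$records$parity[coh$records$sex == 0])))
  }
})

test_that("adding a variable does not perturb earlier columns", {
  # substream seeding: the same (group, variable) index draws the same values
  # regardless of what is drawn afterwards
  s1 <- walkcap:::substream_seed(9, 1, 4)
  s2 <- walkcap:::substream_seed(9, 1, 4)
  expect_identical(s1, s2)
  expect_false(walkcap:::substream_seed(9, 1, 5) == s1)
  expect_false(walkcap:::substream_seed(9, 2, 4) == s1)
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("simulated power tracks the closed-form t-test benchmark", {
  # At a normal shift alternative the Mann-Whitney test's power sits within
  # a few points of the two-sample t-test's (asymptotic efficiency 0.955),
  # so the analytic t power is the independent benchmark for the simulation.
  analytic <- stats::power.t.test(n = 27, delta = 31, sd = 50)$power
  res <- effect_recovery_experiment(design_point_spec(27, d = 31, s = 50),
                                    replicates = 500, seed = 99)
  expect_lt(abs(res$power - analytic), 0.06)
  expect_true(res$ci95_low <= res$power && res$power <= res$ci95_high)
})

test_that("the effect-recovery experiment enforces its preconditions", {
  expect_error(
    effect_recovery_experiment(calibration_preset(), replicates = 10),
    "at least 100")
})
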