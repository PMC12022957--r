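#' Analysis pipeline: read/generate -> standardize -> derive -> classify -> compare
#'
#' [run_analysis()] orchestrates the whole workflow and emits analogues of
#' the four report tables of a case-control walk study: demographics and
#' habits, walk distance and work, heart-rate responses, and blood
#' pressure / oxygen saturation / dyspnea with the intolerance signs, plus
#' the odds ratios and the effect size of the main outcome.
#'
#' @name pipeline
NULL

#' Analysis configuration
#'
#' Every option defaults to the convention of the emulated study: chi-square
#' without continuity correction, Haldane-Anscombe policy for zero cells,
#' report rounding (integer percent for mean changes, 2 dp for prevalence
#' percentages, 1 dp for odds ratios, 3 dp for effect sizes).
#'
#' @param input Path to a cohort CSV, a `walkcap_cohort`, or `NULL` to
#'   generate from `spec`.
#' @param spec A `walkcap_cohort_spec` used when `input` is `NULL`;
#'   defaults to [calibration_preset()] at `seed`.
#' @param coef Reference-equation coefficients.
#' @param chi2_correct Apply the Yates continuity correction.
#' @param zero_cell_policy Odds-ratio zero-cell policy, see [odds_ratio()].
#' @param rounding Apply report rounding in written table files.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed used when generating the input cohort.
#' @return A list of class `walkcap_config`.
#' @export
analysis_config <- function(input = NULL, spec = NULL,
                            coef = default_coefficients(),
                            chi2_correct = FALSE,
                            zero_cell_policy = "haldane",
                            rounding = TRUE,
                            out_dir = NULL, seed = 1L) {
  structure(list(input = input, spec = spec, coef = coef,
                 chi2_correct = chi2_correct,
                 zero_cell_policy = zero_cell_policy,
                 rounding = rounding, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "walkcap_config")
}

resolve_cohort <- function(config) {
  if (inherits(config$input, "walkcap_cohort")) return(config$input)
  if (is.character(config$input)) return(read_cohort(config$input))
  spec <- config$spec
  if (is.null(spec)) spec <- calibration_preset(seed = config$seed)
  generate_cohort(spec)
}

# One numeric comparison row: summaries per group, mean change, MW test.
compare_numeric <- function(variable, x_case, x_control) {
  sc <- summarize_sample(x_case)
  sg <- summarize_sample(x_control)
  mw <- mann_whitney_u(x_case, x_control)
  tibble::tibble(
    variable = variable,
    n_case = sc$n, mean_case = sc$mean, sd_case = sc$sd,
    ci95_low_case = sc$ci95_low, ci95_high_case = sc$ci95_high,
    median_case = sc$median, normal_case = sc$distribution_normal,
    n_control = sg$n, mean_control = sg$mean, sd_control = sg$sd,
    ci95_low_control = sg$ci95_low, ci95_high_control = sg$ci95_high,
    median_control = sg$median, normal_control = sg$distribution_normal,
    mean_change_pct = mean_percentage_change(sc$mean, sg$mean),
    test = "mann_whitney", statistic = mw$U, p_value = mw$p
  )
}

# One categorical comparison row: counts, prevalences, chi-square.
compare_categorical <- function(variable, k_case, n_case, k_control,
                                n_control, correct = FALSE) {
  res <- tryCatch(
    chi2_test(k_case, n_case - k_case, k_control, n_control - k_control,
              correct = correct),
    error = function(e) list(statistic = NA_real_, p = NA_real_,
                             expected_lt5 = NA)
  )
  tibble::tibble(
    variable = variable,
    count_case = k_case, n_case = n_case,
    pct_case = 100 * k_case / n_case,
    count_control = k_control, n_control = n_control,
    pct_control = 100 * k_control / n_control,
    test = "chi2", statistic = res$statistic, p_value = res$p,
    expected_lt5 = res$expected_lt5
  )
}

#' Run the full case-control analysis
#'
#' @param config An [analysis_config()].
#' @return A report bundle (list): `cohort`, `metrics`, `signs`, the four
#'   comparison tables (`demographics`, `walk`, `heart_rate`,
#'   `bp_spo2_dyspnea`), `sign_comparison`, `odds_ratios`, `effect_sizes`,
#'   `within_group_age`, `skipped`, `summary` (the JSON-ready list). When
#'   `config$out_dir` is set, CSV, markdown and JSON files are written
#'   there along with a run log.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "walkcap_config"))
  t0 <- Sys.time()
  cohort <- resolve_cohort(config)
  sizes <- group_sizes(cohort)
  if (any(sizes < 2))
    stop("analysis requires at least 2 participants per group; got ",
         sizes[["case"]], " case / ", sizes[["control"]], " control",
         call. = FALSE)

  metrics <- derive_metrics(cohort, config$coef)
  signs <- classify_signs(cohort, metrics)
  r <- cohort$records
  is_case <- r$group == "case"
  pick <- function(v) list(case = v[is_case], control = v[!is_case])

  num_row <- function(name, v) {
    s <- pick(v)
    compare_numeric(name, s$case, s$control)
  }
  demographics <- dplyr::bind_rows(
    num_row("chronological_age_years", r$age),
    num_row("ecrmc_age_years", metrics$ecrmc_age_years),
    num_row("delta_age_years", metrics$delta_age_years),
    num_row("height_m", r$height),
    num_row("weight_kg", r$weight),
    num_row("bmi_kg_m2", r$bmi),
    num_row("pack_years", r$pack_years),
    num_row("voorrips_daily", r$voorrips_daily),
    num_row("voorrips_sport", r$voorrips_sport),
    num_row("voorrips_leisure", r$voorrips_leisure),
    num_row("voorrips_total",
            r$voorrips_daily + r$voorrips_sport + r$voorrips_leisure)
  )
  walk <- dplyr::bind_rows(
    num_row("distance_m", r$distance_m),
    num_row("pct_predicted_6mwd", metrics$pct_predicted_6mwd),
    num_row("walk_work_m_kg", metrics$walk_work_m_kg)
  )
  heart_rate <- dplyr::bind_rows(
    num_row("hr_rest_bpm", r$hr_rest),
    num_row("hr_rest_pct_mphr", metrics$hr_rest_pct_mphr),
    num_row("hr_end_bpm", r$hr_end),
    num_row("hr_end_pct_mphr", metrics$hr_end_pct_mphr),
    num_row("delta_hr_pct", metrics$delta_hr_pct)
  )
  bp_spo2_dyspnea <- dplyr::bind_rows(
    num_row("sbp_rest_mmhg", r$sbp_rest),
    num_row("sbp_end_mmhg", r$sbp_end),
    num_row("delta_sbp_pct", metrics$delta_sbp_pct),
    num_row("dbp_rest_mmhg", r$dbp_rest),
    num_row("dbp_end_mmhg", r$dbp_end),
    num_row("delta_dbp_pct", metrics$delta_dbp_pct),
    num_row("spo2_rest_pct", r$spo2_rest),
    num_row("spo2_end_pct", r$spo2_end),
    num_row("delta_spo2_pct", metrics$delta_spo2_pct),
    num_row("spo2_change_points", metrics$spo2_change_points),
    num_row("dyspnea_end_vas", r$dyspnea_end),
    num_row("pci_beats_per_m", metrics$pci_beats_per_m)
  )

  cat_row <- function(name, flag, women_only = FALSE) {
    keep <- if (women_only) r$sex == 1 else rep(TRUE, nrow(r))
    f <- flag[keep]; g <- is_case[keep]
    compare_categorical(name, sum(f[g], na.rm = TRUE), sum(g),
                        sum(f[!g], na.rm = TRUE), sum(!g),
                        correct = config$chi2_correct)
  }
  sign_comparison <- dplyr::bind_rows(
    cat_row("woman", r$sex == 1),
    cat_row("smoker", signs$smoker),
    cat_row("sedentary", signs$sedentary),
    cat_row("high_parity", signs$high_parity, women_only = TRUE),
    cat_row("low_schooling", r$schooling_level == "low"),
    cat_row("unfavorable_ses", r$socioeconomic_level == "unfavorable"),
    cat_row("under_40", r$age < 40),
    cat_row("abnormal_6mwd", signs$abnormal_6mwd),
    cat_row("stopped_during_walk", signs$stopped_during_walk),
    cat_row("high_dyspnea_end", signs$high_dyspnea_end),
    cat_row("desaturation", signs$desaturation),
    cat_row("chronotropic_insufficiency", signs$chronotropic_insufficiency)
  )

  or_for <- function(flag) {
    odds_ratio(sum(flag[is_case]), sum(is_case) - sum(flag[is_case]),
               sum(flag[!is_case]), sum(!is_case) - sum(flag[!is_case]),
               zero_cell_policy = config$zero_cell_policy)
  }
  odds_ratios <- list(
    abnormal_6mwd = or_for(signs$abnormal_6mwd),
    chronotropic_insufficiency = or_for(signs$chronotropic_insufficiency)
  )

  g_for <- function(v) {
    s <- pick(v)
    hedges_g(mean(s$case), stats::sd(s$case), length(s$case),
             mean(s$control), stats::sd(s$control), length(s$control))
  }
  effect_sizes <- list(
    distance_m = g_for(r$distance_m),
    pct_predicted_6mwd = g_for(metrics$pct_predicted_6mwd)
  )

  within_group_age <- dplyr::bind_rows(lapply(c("case", "control"), function(g) {
    keep <- r$group == g
    wt <- wilcoxon_paired(r$age[keep], metrics$ecrmc_age_years[keep])
    tibble::tibble(group = g, test = "wilcoxon_paired",
                   statistic = wt$statistic, p_value = wt$p,
                   degenerate = wt$degenerate)
  }))

  skipped <- tibble::tibble(
    variable = c("dyspnea_rest_vas", "delta_dyspnea_pct", "parity"),
    reason = c("constant zero at rest in both groups",
               "undefined: rest dyspnea is 0 (division by zero)",
               "women only; compared via the high_parity prevalence")
  )

  summary <- list(
    n_case = unname(sizes[["case"]]),
    n_control = unname(sizes[["control"]]),
    odds_ratios = lapply(odds_ratios, function(o)
      o[c("or", "ci95_low", "ci95_high", "corrected")]),
    effect_sizes = lapply(effect_sizes, function(e)
      e[c("g", "label")]),
    sign_prevalence_pct = stats::setNames(
      as.list(sign_comparison$pct_case),
      paste0(sign_comparison$variable, "_case")),
    ecrmc_age = list(
      case_mean = mean(metrics$ecrmc_age_years[is_case]),
      control_mean = mean(metrics$ecrmc_age_years[!is_case])),
    delta_age = list(
      case_mean = mean(metrics$delta_age_years[is_case]),
      control_mean = mean(metrics$delta_age_years[!is_case])),
    seed = config$seed
  )

  bundle <- list(cohort = cohort, metrics = metrics, signs = signs,
                 demographics = demographics, walk = walk,
                 heart_rate = heart_rate,
                 bp_spo2_dyspnea = bp_spo2_dyspnea,
                 sign_comparison = sign_comparison,
                 odds_ratios = odds_ratios, effect_sizes = effect_sizes,
                 within_group_age = within_group_age,
                 skipped = skipped, summary = summary, config = config)
  class(bundle) <- "walkcap_report"

  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir, t0)
  invisible(bundle)
}

round_numeric_table <- function(tbl) {
  dplyr::mutate(
    tbl,
    dplyr::across(dplyr::any_of("mean_change_pct"), ~ round(.x)),
    dplyr::across(dplyr::any_of(c("pct_case", "pct_control")),
                  ~ round(.x, 2)),
    dplyr::across(dplyr::where(is.numeric) &
                    !dplyr::any_of(c("mean_change_pct", "pct_case",
                                     "pct_control")),
                  ~ round(.x, 3))
  )
}

md_table <- function(tbl) {
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), as.character))
  header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
  rows <- apply(tbl, 1, function(x)
    paste0("| ", paste(ifelse(is.na(x), "", x), collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

write_report <- function(bundle, out_dir, t0 = Sys.time()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- bundle$config
  per_part <- dplyr::left_join(
    bundle$metrics,
    dplyr::select(bundle$signs, -dplyr::any_of("group")),
    by = "id")
  readr::write_csv(per_part, file.path(out_dir, "participant_metrics.csv"),
                   na = "", progress = FALSE)

  tables <- list(table1_demographics = bundle$demographics,
                 table2_walk = bundle$walk,
                 table3_heart_rate = bundle$heart_rate,
                 table4_bp_spo2_dyspnea = bundle$bp_spo2_dyspnea,
                 signs_prevalence = bundle$sign_comparison)
  md <- character()
  for (nm in names(tables)) {
    tbl <- tables[[nm]]
    if (config$rounding) tbl <- round_numeric_table(tbl)
    readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")),
                     na = "", progress = FALSE)
    md <- c(md, paste0("## ", nm), "", md_table(tbl), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))

  summary <- bundle$summary
  if (config$rounding) {
    summary$odds_ratios <- lapply(summary$odds_ratios, function(o) {
      o$or <- round(o$or, 1); o
    })
    summary$effect_sizes <- lapply(summary$effect_sizes, function(e) {
      e$g <- round(e$g, 3); e
    })
    summary$sign_prevalence_pct <-
      lapply(summary$sign_prevalence_pct, round, 2)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("walkcap %s", as.character(utils::packageVersion("walkcap"))),
    sprintf("seed: %d", config$seed),
    sprintf("n: %d case / %d control", summary$n_case, summary$n_control),
    sprintf("chi2_correct: %s; zero_cell_policy: %s; rounding: %s",
            config$chi2_correct, config$zero_cell_policy, config$rounding),
    sprintf("elapsed_s: %.2f", as.numeric(Sys.time() - t0, units = "secs"))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.walkcap_report <- function(x, ...) {
  cat("<walkcap_report> ", x$summary$n_case, " case / ",
      x$summary$n_control, " control\n", sep = "")
  cat("OR abnormal 6MWD: ",
      round(x$odds_ratios$abnormal_6mwd$or, 1),
      "; OR chronotropic insufficiency: ",
      round(x$odds_ratios$chronotropic_insufficiency$or, 1), "\n", sep = "")
  cat("Hedges g (6MWD, m): ", round(x$effect_sizes$distance_m$g, 3),
      " (", x$effect_sizes$distance_m$label, ")\n", sep = "")
  invisible(x)
}
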