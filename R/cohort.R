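#' Cohort data model
#'
#' A `walkcap_cohort` holds one validated case-control cohort: a tibble of
#' participant records (one row each), a provenance tag, and an exclusion log.
#' Rows that fail validation are never silently dropped; they are moved to the
#' exclusion log with a machine-readable reason, mirroring how incomplete
#' participant files are excluded (not imputed) in field studies.
#'
#' @name cohort
NULL

# Canonical CSV schema: column -> required? The order is also the write order.
cohort_schema <- function() {
  c(id = TRUE, group = TRUE, sex = TRUE, age = TRUE, height = TRUE,
    weight = TRUE, bmi = FALSE, parity = FALSE, pack_years = TRUE,
    voorrips_daily = TRUE, voorrips_sport = TRUE, voorrips_leisure = TRUE,
    schooling_level = TRUE, socioeconomic_level = TRUE,
    distance_m = TRUE, stops = TRUE, hr_rest = TRUE, hr_end = TRUE,
    spo2_rest = TRUE, spo2_end = TRUE, sbp_rest = TRUE, sbp_end = TRUE,
    dbp_rest = TRUE, dbp_end = TRUE, dyspnea_rest = TRUE, dyspnea_end = TRUE)
}

sex_alias_table <- function() {
  c("0" = 0, "1" = 1, "m" = 0, "f" = 1, "man" = 0, "woman" = 1,
    "male" = 0, "female" = 1)
}

group_alias_table <- function() {
  c(case = "case", control = "control", chb = "case", cg = "control")
}

new_cohort <- function(records, exclusion_log, provenance = "unknown") {
  structure(
    list(records = records, exclusion_log = exclusion_log,
         provenance = provenance),
    class = "walkcap_cohort"
  )
}

empty_records <- function() {
  cols <- names(cohort_schema())
  chr <- c("id", "group", "schooling_level", "socioeconomic_level")
  out <- lapply(cols, function(nm) if (nm %in% chr) character() else numeric())
  names(out) <- cols
  tibble::as_tibble(out)
}

empty_exclusion_log <- function() {
  tibble::tibble(id = character(), reason = character())
}

#' @export
print.walkcap_cohort <- function(x, ...) {
  n <- table(factor(x$records$group, levels = c("case", "control")))
  cat("<walkcap_cohort> ", nrow(x$records), " participants (",
      n[["case"]], " case / ", n[["control"]], " control), ",
      nrow(x$exclusion_log), " excluded", "\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# One row -> either a normalized row (list) or a character reason.
# Height is accepted in cm or m: values > 3 are interpreted as centimeters.
validate_row <- function(row) {
  need <- names(cohort_schema())[cohort_schema()]
  for (nm in need) {
    if (is.na(row[[nm]]) || (is.character(row[[nm]]) && !nzchar(row[[nm]])))
      return(paste0(nm, " missing"))
  }

  sx <- sex_alias_table()[tolower(as.character(row$sex))]
  if (is.na(sx)) return(paste0("sex value '", row$sex, "' not recognized"))
  row$sex <- unname(sx)

  gr <- group_alias_table()[tolower(as.character(row$group))]
  if (is.na(gr)) return(paste0("group value '", row$group, "' not recognized"))
  row$group <- unname(gr)

  num_cols <- setdiff(names(cohort_schema()),
                      c("id", "group", "sex", "schooling_level",
                        "socioeconomic_level"))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(row[[nm]]))
    if (!is.na(row[[nm]]) && is.na(v))
      return(paste0(nm, " not numeric: '", row[[nm]], "'"))
    row[[nm]] <- v
  }

  if (row$height > 3) row$height <- row$height / 100
  if (is.na(row$bmi)) row$bmi <- row$weight / row$height^2

  rng <- list(age = c(18, 90), height = c(1.2, 2.2), weight = c(30, 200),
              spo2_rest = c(50, 100), spo2_end = c(50, 100),
              dyspnea_rest = c(0, 10), dyspnea_end = c(0, 10))
  for (nm in names(rng)) {
    if (row[[nm]] < rng[[nm]][1] || row[[nm]] > rng[[nm]][2])
      return(sprintf("%s out of [%g,%g]", nm, rng[[nm]][1], rng[[nm]][2]))
  }
  pos <- c("distance_m", "hr_rest", "hr_end")
  for (nm in pos) if (row[[nm]] <= 0) return(paste0(nm, " must be positive"))
  if (row$pack_years < 0) return("pack_years must be nonnegative")
  if (row$stops < 0 || row$stops != round(row$stops))
    return("stops must be a nonnegative integer")
  for (nm in c("voorrips_daily", "voorrips_sport", "voorrips_leisure"))
    if (row[[nm]] < 0) return(paste0(nm, " must be nonnegative"))

  if (abs(row$bmi - row$weight / row$height^2) > 0.5)
    return("bmi disagrees with weight/height^2 by more than 0.5 kg/m^2")

  if (row$sex == 1) {
    if (is.na(row$parity)) return("parity missing for a woman")
    if (row$parity < 0 || row$parity != round(row$parity))
      return("parity must be a nonnegative integer")
  } else {
    # men carry no parity; a stray value is dropped, not an error
    row$parity <- NA_real_
  }

  for (nm in c("schooling_level", "socioeconomic_level"))
    row[[nm]] <- tolower(as.character(row[[nm]]))
  if (!row$schooling_level %in% c("low", "high"))
    return("schooling_level must be low or high")
  if (!row$socioeconomic_level %in% c("unfavorable", "favorable"))
    return("socioeconomic_level must be unfavorable or favorable")

  row
}

#' Build a validated cohort from a participant table
#'
#' Validates each row against the documented schema; valid rows become
#' records, invalid rows land in the exclusion log with a reason. The split
#' is total: record and exclusion counts always sum to the input row count.
#'
#' @param df A data frame with the cohort CSV columns (see [read_cohort()]).
#' @param provenance Free-text source tag.
#' @return A `walkcap_cohort`.
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  cols <- names(cohort_schema())
  unknown <- setdiff(names(df), cols)
  if (length(unknown) > 0)
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing_req <- setdiff(names(cohort_schema())[cohort_schema()], names(df))
  if (length(missing_req) > 0)
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  for (nm in setdiff(cols, names(df))) df[[nm]] <- NA
  df <- df[, cols]

  records <- list()
  log <- list()
  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, ])
    res <- validate_row(row)
    if (is.character(res)) {
      log[[length(log) + 1]] <-
        list(id = as.character(row$id), reason = res)
    } else {
      res$id <- as.character(res$id)
      records[[length(records) + 1]] <- res
    }
  }
  rec_tbl <- if (length(records) > 0)
    dplyr::bind_rows(lapply(records, tibble::as_tibble)) else empty_records()
  log_tbl <- if (length(log) > 0)
    dplyr::bind_rows(lapply(log, tibble::as_tibble)) else empty_exclusion_log()
  if (anyDuplicated(rec_tbl$id) > 0)
    stop("duplicate participant ids: ",
         paste(unique(rec_tbl$id[duplicated(rec_tbl$id)]), collapse = ", "),
         call. = FALSE)
  new_cohort(rec_tbl, log_tbl, provenance)
}

#' Read a cohort CSV
#'
#' Reads a comma-separated UTF-8 file with "." as the decimal mark (no
#' locale-dependent parsing) and validates it into a [cohort]. Sex accepts the
#' aliases `0/1`, `M/F`, `man/woman`, `male/female` (case-insensitive); group
#' accepts `case/control` and `CHB/CG`. Height may be given in cm or m
#' (values above 3 are treated as cm and converted). A missing `bmi` is
#' recomputed from weight and height. Rejected rows are logged, never
#' dropped.
#'
#' @param path Path to the CSV file.
#' @param schema_version Schema identifier; only `"1"` is defined.
#' @return A `walkcap_cohort`; rejected rows appear in `$exclusion_log`.
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1"))
    stop("unknown schema_version: ", schema_version, call. = FALSE)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        locale = readr::locale(decimal_mark = "."),
                        progress = FALSE)
  as_cohort(df, provenance = path)
}

#' Write a cohort CSV
#'
#' Writes the validated records so that [read_cohort()] reproduces the cohort
#' field-for-field. A man's absent parity is written as an empty cell, not 0.
#'
#' @param cohort A `walkcap_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "walkcap_cohort"))
  readr::write_csv(cohort$records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Number of participants per group
#' @param cohort A `walkcap_cohort`.
#' @return Named integer vector with entries `case` and `control`.
#' @export
group_sizes <- function(cohort) {
  tab <- table(factor(cohort$records$group, levels = c("case", "control")))
  c(case = unname(tab[["case"]]), control = unname(tab[["control"]]))
}
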