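#' Construct a cohort object
#'
#' A cohort bundles the per-patient baseline table with the longitudinal
#' visit stream. Both tables are validated: enum fields must use the
#' documented lowercase labels, pressures must be positive, visit days must
#' be strictly increasing within a patient, and every visit must reference
#' a baseline patient.
#'
#' @param baseline Data frame with one row per patient (columns
#'   `patient_id`, `age`, `gender`, `ethnicity`, `diagnosis`, `lens_status`,
#'   `shaffer_grade`, `vf_stage`, `cup_disc`, `va_logmar`, `baseline_iop`,
#'   `baseline_meds`, `surgery`).
#' @param visits Data frame with one row per follow-up observation (columns
#'   `patient_id`, `day`, `iop`, `meds`, `secondary_surgery`).
#' @param provenance Optional list echoing the generating configuration and
#'   seed (attached by [generate_cohort()]).
#' @return An object of class `gi_cohort`: a list with elements `baseline`
#'   and `visits` (tibbles) and a `provenance` attribute.
#' @export
new_cohort <- function(baseline, visits, provenance = NULL) {
  baseline <- tibble::as_tibble(baseline)
  visits <- tibble::as_tibble(visits)
  validate_cohort_tables(baseline, visits)
  out <- list(baseline = baseline, visits = visits)
  attr(out, "provenance") <- provenance
  class(out) <- "gi_cohort"
  out
}

#' @export
print.gi_cohort <- function(x, ...) {
  cat(sprintf("<gi_cohort> %d patients, %d visits\n",
              nrow(x$baseline), nrow(x$visits)))
  prov <- attr(x, "provenance")
  if (!is.null(prov$seed)) cat(sprintf("  generated with seed %s\n", prov$seed))
  invisible(x)
}

fail_rows <- function(what, bad, context) {
  rows <- which(bad)
  stop(sprintf("%s: %s at row(s) %s", context, what,
               paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
}

validate_baseline_table <- function(baseline, context = "baseline table") {
  miss <- setdiff(baseline_columns, names(baseline))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(baseline) == 0) return(invisible(baseline))
  if (anyDuplicated(baseline$patient_id)) {
    fail_rows("duplicate patient_id", duplicated(baseline$patient_id), context)
  }
  bad_age <- !is.finite(baseline$age) | baseline$age < 18 | baseline$age > 96
  if (any(bad_age)) fail_rows("age outside 18..96", bad_age, context)
  bad_iop <- !is.finite(baseline$baseline_iop) | baseline$baseline_iop <= 0
  if (any(bad_iop)) fail_rows("non-positive baseline_iop", bad_iop, context)
  bad_med <- !is.finite(baseline$baseline_meds) | baseline$baseline_meds < 0 |
    baseline$baseline_meds != round(baseline$baseline_meds)
  if (any(bad_med)) {
    fail_rows("baseline_meds not a non-negative whole number", bad_med, context)
  }
  bad_cd <- !is.finite(baseline$cup_disc) | baseline$cup_disc < 0 |
    baseline$cup_disc > 2
  if (any(bad_cd)) fail_rows("cup_disc outside [0, 2]", bad_cd, context)
  for (field in c("gender", "ethnicity", "diagnosis", "lens_status",
                  "shaffer_grade", "vf_stage", "surgery")) {
    bad <- !(as.character(baseline[[field]]) %in% gi_levels[[field]])
    if (any(bad)) {
      fail_rows(sprintf("unknown %s label '%s'", field,
                        as.character(baseline[[field]])[which(bad)[1]]),
                bad, context)
    }
  }
  invisible(baseline)
}

validate_visit_table <- function(visits, patient_ids,
                                 context = "visit table") {
  miss <- setdiff(visit_columns, names(visits))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(visits) == 0) return(invisible(visits))
  bad_day <- !is.finite(visits$day) | visits$day < 0 |
    visits$day != round(visits$day)
  if (any(bad_day)) fail_rows("day not a non-negative whole number",
                              bad_day, context)
  bad_iop <- !is.finite(visits$iop) | visits$iop <= 0
  if (any(bad_iop)) fail_rows("non-positive iop", bad_iop, context)
  bad_med <- !is.finite(visits$meds) | visits$meds < 0 |
    visits$meds != round(visits$meds)
  if (any(bad_med)) fail_rows("meds not a non-negative whole number",
                              bad_med, context)
  if (!is.logical(visits$secondary_surgery) ||
      anyNA(visits$secondary_surgery)) {
    stop(sprintf("%s: secondary_surgery must be TRUE/FALSE with no missing",
                 context), call. = FALSE)
  }
  orphan <- !(visits$patient_id %in% patient_ids)
  if (any(orphan)) {
    fail_rows(sprintf("visit references unknown patient '%s'",
                      visits$patient_id[which(orphan)[1]]), orphan, context)
  }
  # file order within a patient must already be strictly increasing
  same <- visits$patient_id[-1] == visits$patient_id[-nrow(visits)]
  nondec <- diff(visits$day) <= 0
  if (length(same) && any(same & nondec)) {
    bad_row <- which(same & nondec)[1] + 1
    fail_rows("visit days not strictly increasing within patient",
              seq_len(nrow(visits)) == bad_row, context)
  }
  invisible(visits)
}

validate_cohort_tables <- function(baseline, visits) {
  validate_baseline_table(baseline)
  validate_visit_table(visits, baseline$patient_id)
  invisible(NULL)
}

#' Read a cohort from delimited files
#'
#' Reads the baseline and visit CSV files written by [write_cohort()] (or
#' prepared externally with the same schema) and validates them. Malformed
#' rows raise errors naming the offending row.
#'
#' @param baseline_path Path to the baseline CSV.
#' @param visits_path Path to the visits CSV.
#' @return A `gi_cohort` object.
#' @export
read_cohort <- function(baseline_path, visits_path) {
  for (p in c(baseline_path, visits_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  baseline <- readr::read_csv(
    baseline_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      gender = readr::col_character(),
      ethnicity = readr::col_character(),
      diagnosis = readr::col_character(),
      lens_status = readr::col_character(),
      shaffer_grade = readr::col_character(),
      vf_stage = readr::col_character(),
      surgery = readr::col_character(),
      .default = readr::col_double()
    ))
  visits <- readr::read_csv(
    visits_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      secondary_surgery = readr::col_logical(),
      .default = readr::col_double()
    ))
  new_cohort(baseline, visits)
}

#' Write a cohort to delimited files
#'
#' Writes `baseline.csv` and `visits.csv`. The round trip through
#' [read_cohort()] is lossless.
#'
#' @param cohort A `gi_cohort` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gi_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(baseline = file.path(dir, "baseline.csv"),
             visits = file.path(dir, "visits.csv"))
  readr::write_csv(cohort$baseline, paths[["baseline"]], progress = FALSE)
  readr::write_csv(cohort$visits, paths[["visits"]], progress = FALSE)
  invisible(paths)
}
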