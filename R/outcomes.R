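#' Per-patient outcome measures at one year
#'
#' For each patient, takes the visit closest to `target_day` within
#' `window` days and computes the IOP and medication reductions against
#' baseline (positive = improvement). Patients with no qualifying visit
#' (short-term follow-up) are excluded; the exclusion count is attached as
#' the attribute `n_excluded` and reported via `message()`.
#'
#' @param cohort A `gi_cohort` object.
#' @param target_day Follow-up target in days (default 365).
#' @param window Acceptance window around the target (default 90 days).
#' @param quiet Suppress the exclusion message.
#' @return A tibble with `patient_id`, `gi_group`, `followup_day`,
#'   `iop_12mo`, `iop_reduction_12mo`, `med_reduction_12mo`; attribute
#'   `n_excluded`.
#' @export
compute_outcomes <- function(cohort, target_day = 365, window = 90,
                             quiet = FALSE) {
  stopifnot(inherits(cohort, "gi_cohort"))
  bl <- score_baseline(cohort$baseline)
  v <- cohort$visits
  if (nrow(v) > 0) {
    v <- v[abs(v$day - target_day) <= window, ]
  }
  if (nrow(v) > 0) {
    v <- dplyr::slice_min(dplyr::group_by(v, .data$patient_id),
                          abs(.data$day - target_day), n = 1,
                          with_ties = FALSE)
    v <- dplyr::ungroup(v)
  }
  keep <- match(v$patient_id, bl$patient_id)
  out <- tibble::tibble(
    patient_id = v$patient_id,
    gi_group = bl$gi_group[keep],
    followup_day = v$day,
    iop_12mo = v$iop,
    iop_reduction_12mo = bl$baseline_iop[keep] - v$iop,
    med_reduction_12mo = bl$baseline_meds[keep] - v$meds
  )
  out <- out[order(match(out$patient_id, bl$patient_id)), ]
  n_excl <- nrow(bl) - nrow(out)
  if (n_excl > 0 && !quiet) {
    message(sprintf(
      "%d patient(s) excluded: no visit within %d days of day %d",
      n_excl, window, target_day))
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Per-visit group trajectories
#'
#' Mean and SD of IOP and medication count at each scheduled day, by
#' severity group — the longitudinal trajectory summaries.
#'
#' @param cohort A `gi_cohort` object.
#' @return A tibble with `gi_group`, `day`, `n`, `iop_mean`, `iop_sd`,
#'   `meds_mean`, `meds_sd`.
#' @export
summarize_visits <- function(cohort) {
  stopifnot(inherits(cohort, "gi_cohort"))
  bl <- score_baseline(cohort$baseline)
  v <- cohort$visits
  v$gi_group <- bl$gi_group[match(v$patient_id, bl$patient_id)]
  dplyr::ungroup(dplyr::summarise(
    dplyr::group_by(v, .data$gi_group, .data$day),
    n = dplyr::n(),
    iop_mean = mean(.data$iop), iop_sd = stats::sd(.data$iop),
    meds_mean = mean(.data$meds), meds_sd = stats::sd(.data$meds),
    .groups = "drop"))
}

# Reference levels for dummy coding; absent levels in a fitted table mean
# the level is the comparator.
reference_levels <- c(gender = "female", ethnicity = "african_american",
                      diagnosis = "poag", lens_status = "phakic",
                      surgery = "trabectome_alone")

default_screen_covariates <- c("age", "gender", "ethnicity", "diagnosis",
                               "cup_disc", "shaffer_grade", "lens_status",
                               "surgery")

# Builds the regression frame: outcome joined to baseline covariates,
# factors releveled to their references, shaffer_grade as ordinal 1-4,
# not_recorded treated as missing.
regression_frame <- function(outcomes, baseline, covariates) {
  if (!("gi_group" %in% names(baseline))) baseline <- score_baseline(baseline)
  keep <- match(outcomes$patient_id, baseline$patient_id)
  if (anyNA(keep)) {
    stop("outcomes reference patients absent from the baseline table",
         call. = FALSE)
  }
  df <- data.frame(iop_reduction_12mo = outcomes$iop_reduction_12mo,
                   gi_group = as.numeric(baseline$gi_group[keep]))
  for (cv in covariates) {
    if (!(cv %in% names(baseline))) {
      stop(sprintf("unknown covariate '%s'", cv), call. = FALSE)
    }
    x <- baseline[[cv]][keep]
    if (cv == "shaffer_grade") {
      x <- match(as.character(x), c("I", "II", "III", "IV"))  # NR -> NA
    } else if (cv %in% names(reference_levels)) {
      x <- as.character(x)
      x[x == "not_recorded"] <- NA
      lv <- setdiff(gi_levels[[cv]], "not_recorded")
      x <- factor(x, levels = union(reference_levels[[cv]], lv))
    }
    df[[cv]] <- x
  }
  df
}

tidy_lm <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' Univariate screen of covariates against IOP reduction
#'
#' Fits one simple linear regression of the 12-month IOP reduction on each
#' covariate (continuous as-is, categoricals dummy-coded against their
#' reference level, Shaffer grade as ordinal 1-4, `not_recorded` treated as
#' missing). A covariate is flagged `selected` when any of its terms has
#' p below `alpha`. Constant covariates are skipped with a warning.
#'
#' @param outcomes Output of [compute_outcomes()].
#' @param baseline Baseline table (scored or not).
#' @param covariates Covariates to screen.
#' @param alpha Selection threshold (default 0.05).
#' @return A tibble of per-term results (`covariate`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `n_used`, `selected`) of class
#'   `gi_screen`; `attr(, "selected")` holds the selected covariate names.
#' @export
univariate_screen <- function(outcomes, baseline,
                              covariates = default_screen_covariates,
                              alpha = 0.05) {
  rows <- list()
  selected <- character()
  for (cv in covariates) {
    df <- regression_frame(outcomes, baseline, cv)
    df <- df[stats::complete.cases(df[c("iop_reduction_12mo", cv)]), ]
    x <- df[[cv]]
    n_distinct <- length(unique(x[!is.na(x)]))
    if (n_distinct < 2) {
      warning(sprintf("covariate '%s' is constant; skipped", cv),
              call. = FALSE)
      next
    }
    if (is.factor(x)) df[[cv]] <- droplevels(x)
    fit <- stats::lm(stats::reformulate(cv, "iop_reduction_12mo"), data = df)
    td <- tidy_lm(fit)
    td <- td[td$term != "(Intercept)", ]
    td$covariate <- cv
    td$n_used <- nrow(df)
    sel <- any(td$p_value < alpha)
    td$selected <- sel
    if (sel) selected <- c(selected, cv)
    rows[[cv]] <- td
  }
  out <- dplyr::bind_rows(rows)
  out <- out[c("covariate", "term", "estimate", "std_error", "statistic",
               "p_value", "n_used", "selected")]
  attr(out, "selected") <- selected
  attr(out, "alpha") <- alpha
  class(out) <- c("gi_screen", class(out))
  out
}

#' Multivariate regression of IOP reduction
#'
#' Fits a single ordinary least squares model of the 12-month IOP
#' reduction on the severity group (entered as a linear ordinal 1-4 term —
#' one coefficient per group level) plus the supplied covariates. The
#' severity group and the surgery type (the study's design variable) are
#' always included. Rows with missing values in any included covariate are
#' dropped.
#'
#' @param outcomes Output of [compute_outcomes()].
#' @param baseline Baseline table (scored or not).
#' @param covariates Covariates selected for adjustment, e.g.
#'   `attr(univariate_screen(...), "selected")`.
#' @param always_include Terms forced into the model regardless of the
#'   screen (default severity group and surgery type).
#' @return A tibble of per-term results of class `gi_fit` with attributes
#'   `n_used`, `reference_levels`, `model_kind`, and `fit` (the `lm`
#'   object).
#' @export
multivariate_fit <- function(outcomes, baseline, covariates = character(),
                             always_include = c("gi_group", "surgery")) {
  covs <- union(setdiff(always_include, "gi_group"), covariates)
  df <- regression_frame(outcomes, baseline, covs)
  df <- df[stats::complete.cases(df), ]
  for (cv in covs) if (is.factor(df[[cv]])) df[[cv]] <- droplevels(df[[cv]])
  terms <- c(if ("gi_group" %in% always_include) "gi_group", covs)
  fit <- stats::lm(stats::reformulate(terms, "iop_reduction_12mo"), data = df)
  if (anyNA(coef(fit))) {
    stop(sprintf("design matrix is rank deficient; collinear term(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  out <- tidy_lm(fit)
  attr(out, "n_used") <- nrow(df)
  attr(out, "reference_levels") <- reference_levels[
    intersect(names(reference_levels), covs)]
  attr(out, "model_kind") <- "multivariate"
  attr(out, "fit") <- fit
  class(out) <- c("gi_fit", class(out))
  out
}

#' @export
print.gi_fit <- function(x, ...) {
  cat(sprintf("<gi_fit> multivariate OLS, n = %d\n", attr(x, "n_used")))
  print(tibble::as_tibble(x), n = nrow(x))
  refs <- attr(x, "reference_levels")
  if (length(refs)) {
    cat("reference levels:",
        paste(sprintf("%s=%s", names(refs), refs), collapse = ", "), "\n")
  }
  invisible(x)
}
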