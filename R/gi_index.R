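#' Intraocular pressure severity points
#'
#' Bins baseline IOP into four severity points. Bin edges are half-open:
#' \[0, 20), \[20, 30), \[30, 40), \[40, Inf), so an IOP of exactly 40 mmHg
#' scores 4 and fractional pressures in (39, 40) score 3. The integer labels
#' quoted clinically ("20-29 mmHg" and so on) are the inclusive integer
#' ranges of these bins.
#'
#' @param iop Numeric vector of baseline intraocular pressures in mmHg;
#'   must be finite and strictly positive.
#' @return Integer vector of points in 1..4.
#' @examples
#' iop_points(c(19, 20, 29.5, 40, 45))
#' @export
iop_points <- function(iop) {
  if (!is.numeric(iop)) {
    stop("`iop` must be numeric (mmHg).", call. = FALSE)
  }
  bad <- !is.finite(iop) | iop <= 0
  if (any(bad)) {
    stop(sprintf("`iop` must be finite and positive; offending value(s): %s",
                 paste(utils::head(iop[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  findInterval(iop, c(20, 30, 40)) + 1L
}

#' Medication burden severity points
#'
#' Bins the number of glaucoma medications: <=1 scores 1, 2 scores 2,
#' 3 scores 3, >=4 scores 4. Counts must be non-negative whole numbers;
#' fixed-combination drops count as recorded in the input.
#'
#' @param meds Integer-valued vector of medication counts.
#' @return Integer vector of points in 1..4.
#' @examples
#' med_points(c(0, 1, 2, 3, 6))
#' @export
med_points <- function(meds) {
  if (!is.numeric(meds)) {
    stop("`meds` must be numeric (a medication count).", call. = FALSE)
  }
  bad <- !is.finite(meds) | meds < 0 | meds != round(meds)
  if (any(bad)) {
    stop(sprintf(
      "`meds` must be non-negative whole numbers; offending value(s): %s",
      paste(utils::head(meds[bad], 3), collapse = ", ")), call. = FALSE)
  }
  pmin(pmax(as.integer(meds), 1L), 4L)
}

#' Visual-field stage severity points
#'
#' Maps the clinical visual-field stage to points: mild 1, moderate 2,
#' advanced 3, end_stage 4. Staging perimetric indices into these four
#' labels is the data producer's responsibility.
#'
#' @param stage Character vector with values `"mild"`, `"moderate"`,
#'   `"advanced"`, `"end_stage"` (or a factor with those levels).
#' @return Integer vector of points in 1..4.
#' @examples
#' vf_points(c("mild", "end_stage"))
#' @export
vf_points <- function(stage) {
  stage <- as.character(stage)
  map <- c(mild = 1L, moderate = 2L, advanced = 3L, end_stage = 4L)
  bad <- !(stage %in% names(map))
  if (any(bad)) {
    stop(sprintf("unknown visual-field stage label(s): %s",
                 paste(unique(utils::head(stage[bad], 3)), collapse = ", ")),
         call. = FALSE)
  }
  unname(map[stage])
}

#' Severity group from a glaucoma index score
#'
#' Buckets the composite index (product of the three component points,
#' range 1..64) into four severity groups: group 1 (mild) GI <= 4,
#' group 2 (moderate) 4 < GI <= 8, group 3 (advanced) 8 < GI <= 16,
#' group 4 (severe) GI > 16.
#'
#' @param gi Integer vector of composite index values in 1..64.
#' @return Integer vector of group labels in 1..4.
#' @examples
#' gi_group(c(4, 8, 16, 18))
#' @export
gi_group <- function(gi) {
  if (!is.numeric(gi)) {
    stop("`gi` must be numeric.", call. = FALSE)
  }
  bad <- !is.finite(gi) | gi < 1 | gi > 64 | gi != round(gi)
  if (any(bad)) {
    stop(sprintf("`gi` must be whole numbers in 1..64; offending value(s): %s",
                 paste(utils::head(gi[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  findInterval(gi, c(4, 8, 16), left.open = TRUE) + 1L
}

#' Composite glaucoma severity index
#'
#' Computes the per-patient component points, the composite index
#' (the product of IOP, medication, and visual-field points) and the
#' severity group assignment.
#'
#' @param iop Baseline IOP in mmHg (see [iop_points()]).
#' @param meds Baseline medication count (see [med_points()]).
#' @param vf_stage Visual-field stage label (see [vf_points()]).
#' @return A tibble with columns `iop_points`, `med_points`, `vf_points`,
#'   `gi` and `gi_group`, one row per input element.
#' @examples
#' gi_score(iop = 25, meds = 2, vf_stage = "moderate")
#' @export
gi_score <- function(iop, meds, vf_stage) {
  ip <- iop_points(iop)
  mp <- med_points(meds)
  vp <- vf_points(vf_stage)
  n <- unique(c(length(ip), length(mp), length(vp)))
  if (length(n) != 1) {
    stop("`iop`, `meds` and `vf_stage` must have the same length.",
         call. = FALSE)
  }
  gi <- ip * mp * vp
  tibble::tibble(
    iop_points = ip, med_points = mp, vf_points = vp,
    gi = gi, gi_group = gi_group(gi)
  )
}

#' Score a baseline table
#'
#' Appends the severity-index columns (`iop_points`, `med_points`,
#' `vf_points`, `gi`, `gi_group`) to a baseline table.
#'
#' @param baseline A baseline data frame with columns `baseline_iop`,
#'   `baseline_meds`, and `vf_stage` (see [read_cohort()]).
#' @return The input with the five score columns appended.
#' @export
score_baseline <- function(baseline) {
  need <- c("baseline_iop", "baseline_meds", "vf_stage")
  miss <- setdiff(need, names(baseline))
  if (length(miss)) {
    stop(sprintf("baseline table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sc <- gi_score(baseline$baseline_iop, baseline$baseline_meds,
                 baseline$vf_stage)
  baseline <- baseline[setdiff(names(baseline), names(sc))]
  dplyr::bind_cols(tibble::as_tibble(baseline), sc)
}
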