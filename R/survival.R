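# Shared event-construction core. A visit "fails the criterion" when its
# IOP exceeds 21 mmHg AND the reduction from baseline is below 20%. Under
# the confirmed rule the patient fails at the second of the first pair of
# consecutive recorded visits strictly after day 90 that both fail; under
# the single_visit rule, at the first failing visit after day 90. A
# secondary glaucoma surgery fails the patient at its visit day regardless
# of IOP. Otherwise the patient is censored at the last visit day (capped
# at `cap_day` when given).
event_times_internal <- function(baseline_iop, patient_ids, visits,
                                 rule = c("confirmed", "single_visit"),
                                 cap_day = 365) {
  rule <- match.arg(rule)
  if (nrow(visits) == 0 || length(patient_ids) == 0) {
    return(tibble::tibble(patient_id = character(), time = numeric(),
                          event = logical(), cause = character()))
  }
  v <- visits[order(match(visits$patient_id, patient_ids), visits$day), ]
  base <- baseline_iop[match(v$patient_id, patient_ids)]
  fails <- v$iop > 21 & (base - v$iop) < 0.2 * base
  v <- dplyr::mutate(
    dplyr::group_by(
      tibble::tibble(patient_id = v$patient_id, day = v$day, fails = fails,
                     secondary = v$secondary_surgery),
      .data$patient_id),
    prev_day = dplyr::lag(.data$day),
    prev_fails = dplyr::lag(.data$fails))
  v <- dplyr::ungroup(dplyr::summarise(
    dplyr::group_by(v, .data$patient_id),
    iop_day = if (rule == "confirmed") {
      suppressWarnings(min(.data$day[.data$day > 90 & .data$fails &
        !is.na(.data$prev_day) & .data$prev_day > 90 &
        !is.na(.data$prev_fails) & .data$prev_fails]))
    } else {
      suppressWarnings(min(.data$day[.data$day > 90 & .data$fails]))
    },
    sec_day = suppressWarnings(min(.data$day[.data$secondary])),
    last_day = max(.data$day),
    .groups = "drop"))
  # min() over empty sets yields Inf: no qualifying failure
  keep <- match(patient_ids, v$patient_id)
  v <- v[keep[!is.na(keep)], ]
  event <- is.finite(v$iop_day) | is.finite(v$sec_day)
  time <- ifelse(event, pmin(v$iop_day, v$sec_day),
                 if (is.null(cap_day)) v$last_day else
                   pmin(v$last_day, cap_day))
  cause <- ifelse(!event, "censored",
                  ifelse(v$sec_day <= v$iop_day, "secondary_surgery",
                         "iop_criterion"))
  tibble::tibble(patient_id = v$patient_id, time = as.numeric(time),
                 event = event, cause = cause)
}

#' Construct surgical success/failure events from visit streams
#'
#' Applies the surgical-success criterion (success: IOP at most 21 mmHg or
#' at least a 20% reduction from baseline, and no secondary glaucoma
#' surgery) to each patient's visit stream. Under the default `"confirmed"`
#' rule a patient fails at the second of the first pair of consecutive
#' recorded visits after three months (strictly after day 90) that both
#' violate the criterion; the event is not established until the
#' confirmation visit. The complementary `"single_visit"` reading (failure
#' at the first qualifying visit) is available as an option. A
#' secondary-surgery flag fails the patient at that visit's day regardless
#' of IOP. Patients without a qualifying failure are censored at their last
#' visit day, capped at `cap_day`.
#'
#' @param cohort A `gi_cohort` object.
#' @param rule `"confirmed"` (default) or `"single_visit"`.
#' @param cap_day Administrative censoring day for censored patients
#'   (default 365); `NULL` retains the full follow-up.
#' @return A tibble with columns `patient_id`, `time` (days), `event`
#'   (`TRUE` = failure), `cause` (`"iop_criterion"`, `"secondary_surgery"`
#'   or `"censored"`), and `gi_group`.
#' @export
classify_events <- function(cohort, rule = c("confirmed", "single_visit"),
                            cap_day = 365) {
  stopifnot(inherits(cohort, "gi_cohort"))
  rule <- match.arg(rule)
  ev <- event_times_internal(cohort$baseline$baseline_iop,
                             cohort$baseline$patient_id, cohort$visits,
                             rule = rule, cap_day = cap_day)
  sc <- gi_score(cohort$baseline$baseline_iop, cohort$baseline$baseline_meds,
                 cohort$baseline$vf_stage)
  ev$gi_group <- sc$gi_group[match(ev$patient_id,
                                   cohort$baseline$patient_id)]
  ev
}

#' Kaplan-Meier survival curves by severity group
#'
#' Product-limit estimate of the surgical-success survival function per
#' severity group, with failures preceding censorings at tied times.
#'
#' @param events Event tibble from [classify_events()] (columns `time`,
#'   `event`, `gi_group`).
#' @return An object of class `gi_km`: list with `curves` (tibble of
#'   `gi_group`, `time`, `n_risk`, `n_event`, `survival`) and `s_12mo`
#'   (tibble of `gi_group` and the survival probability at day 365).
#' @export
km_estimate <- function(events) {
  if (!all(c("time", "event", "gi_group") %in% names(events))) {
    stop("`events` must have columns time, event, gi_group", call. = FALSE)
  }
  if (nrow(events) == 0) stop("no event records", call. = FALSE)
  groups <- sort(unique(events$gi_group))
  curves <- list()
  s12 <- numeric(length(groups))
  for (i in seq_along(groups)) {
    e <- events[events$gi_group == groups[i], ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = e)
    curves[[i]] <- tibble::tibble(
      gi_group = groups[i], time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, survival = fit$surv
    )
    s12[i] <- summary(fit, times = 365, extend = TRUE)$surv
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 s_12mo = tibble::tibble(gi_group = groups, s_12mo = s12)),
            class = "gi_km")
}

#' @export
print.gi_km <- function(x, ...) {
  cat("<gi_km> Kaplan-Meier surgical-success curves\n")
  cat("  12-month survival by severity group:\n")
  for (i in seq_len(nrow(x$s_12mo))) {
    cat(sprintf("    group %d: %.1f%%\n", x$s_12mo$gi_group[i],
                100 * x$s_12mo$s_12mo[i]))
  }
  invisible(x)
}

#' Plot Kaplan-Meier curves by severity group
#'
#' @param x A `gi_km` object.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics lines legend
#' @export
plot.gi_km <- function(x, ...) {
  groups <- x$s_12mo$gi_group
  cols <- c("forestgreen", "goldenrod2", "darkorange2", "firebrick")
  plot(NA, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
       xlab = "Days after surgery", ylab = "Proportion surviving (success)",
       main = "Surgical success by severity group", ...)
  for (i in seq_along(groups)) {
    cv <- x$curves[x$curves$gi_group == groups[i], ]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)),
                    do.points = FALSE, col = cols[(groups[i] - 1) %% 4 + 1])
  }
  graphics::legend("bottomleft", legend = paste("GI group", groups),
                   col = cols[(groups - 1) %% 4 + 1], lty = 1, bty = "n")
  invisible(x)
}

#' k-sample log-rank test across severity groups
#'
#' Compares the survival distributions of the severity groups with the
#' log-rank chi-square statistic on k-1 degrees of freedom.
#'
#' @param events Event tibble from [classify_events()].
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
log_rank <- function(events) {
  if (!all(c("time", "event", "gi_group") %in% names(events))) {
    stop("`events` must have columns time, event, gi_group", call. = FALSE)
  }
  k <- length(unique(events$gi_group))
  if (k < 2) stop("log-rank test needs at least 2 groups", call. = FALSE)
  if (!any(events$event)) {
    stop("log-rank test undefined: all records censored", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ gi_group,
                            data = events)
  list(statistic = unname(fit$chisq), df = as.integer(k - 1),
       p_value = stats::pchisq(fit$chisq, k - 1, lower.tail = FALSE))
}
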