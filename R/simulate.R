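# IOP bin lower edges by point value; recorded pressures are integers, so
# point a corresponds to the integer range lo[a] .. lo[a] + 9.
iop_bin_lo <- c(10, 20, 30, 40)

# All 64 attainable component-point combinations with their prior weight
# under independent component draws, composite score, and severity group.
component_combos <- function(weights) {
  g <- expand.grid(iop_pts = 1:4, med_pts = 1:4, vf_pts = 1:4)
  gi <- g$iop_pts * g$med_pts * g$vf_pts
  tibble::tibble(
    iop_pts = g$iop_pts, med_pts = g$med_pts, vf_pts = g$vf_pts,
    prior = weights[g$iop_pts] * weights[g$med_pts] * weights[g$vf_pts],
    gi = gi, group = gi_group(gi)
  )
}

#' Generator calibration summary
#'
#' Computes the deterministic calibration quantities the generator derives
#' from a configuration: the conditional component-combination
#' distributions, per-group expected baseline IOP and covariate-effect
#' moments, the latent intercept anchoring the group-4 marginal mean, and
#' the per-group residual SD that makes the marginal reduction SDs match
#' the configured values.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `combos` (tibble of attainable
#'   combinations), `e_base_iop`, `v_base_iop`, `e_effects`, `v_effects`
#'   (length-4 numeric), `intercept` (scalar) and `resid_sd` (length-4).
#' @export
generator_calibration <- function(config) {
  combos <- component_combos(config$component_weights)
  e_b <- v_b <- numeric(4)
  for (g in 1:4) {
    d <- combos[combos$group == g, ]
    if (nrow(d) == 0 || sum(d$prior) <= 0) {
      stop(sprintf("no attainable component combination for group %d", g),
           call. = FALSE)
    }
    w <- d$prior / sum(d$prior)
    mids <- iop_bin_lo[d$iop_pts] + 4.5
    e_b[g] <- sum(w * mids)
    v_b[g] <- sum(w * (mids^2 + (10^2 - 1) / 12)) - e_b[g]^2
  }
  eff <- config$covariate_effects
  dem <- config$demographics
  p_of <- function(tab, level) {
    cs <- colSums(tab)
    ifelse(cs > 0, tab[level, ] / cs, 0)
  }
  p_h <- p_of(dem$ethnicity, "hispanic")
  p_x <- p_of(dem$diagnosis, "pseudoexfoliation")
  p_s <- p_of(dem$diagnosis, "steroid")
  p_p <- p_of(dem$surgery, "phaco_trabectome")
  e_eff <- eff[["hispanic"]] * p_h + eff[["pseudoexfoliation"]] * p_x +
    eff[["steroid"]] * p_s + eff[["phaco"]] * p_p
  v_eff <- eff[["hispanic"]]^2 * p_h * (1 - p_h) +
    eff[["pseudoexfoliation"]]^2 * p_x * (1 - p_x) +
    eff[["steroid"]]^2 * p_s * (1 - p_s) +
    eff[["phaco"]]^2 * p_p * (1 - p_p) -
    2 * eff[["pseudoexfoliation"]] * eff[["steroid"]] * p_x * p_s
  intercept <- config$reduction_means[4] - 4 * config$reduction_per_level -
    e_eff[4]
  resid_var <- config$reduction_sds^2 - v_eff -
    config$baseline_slope^2 * v_b
  list(
    combos = combos,
    e_base_iop = e_b, v_base_iop = v_b,
    e_effects = unname(e_eff), v_effects = unname(v_eff),
    intercept = unname(intercept),
    resid_sd = sqrt(pmax(resid_var, 0.25))
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

sample_levels <- function(tab, group, n_each) {
  # one draw per patient from the group's multinomial column
  out <- character(length(group))
  for (g in 1:4) {
    idx <- which(group == g)
    if (!length(idx)) next
    w <- tab[, g]
    if (sum(w) <= 0) {
      stop(sprintf("demographic table has an all-zero column for group %d", g),
           call. = FALSE)
    }
    out[idx] <- sample(rownames(tab), length(idx), replace = TRUE, prob = w)
  }
  out
}

empty_baseline <- function() {
  tibble::tibble(
    patient_id = character(), age = integer(), gender = character(),
    ethnicity = character(), diagnosis = character(),
    lens_status = character(), shaffer_grade = character(),
    vf_stage = character(), cup_disc = numeric(), va_logmar = numeric(),
    baseline_iop = numeric(), baseline_meds = integer(), surgery = character()
  )
}

empty_visits <- function() {
  tibble::tibble(patient_id = character(), day = integer(), iop = numeric(),
                 meds = integer(), secondary_surgery = logical())
}

#' Generate a synthetic cohort
#'
#' Simulates a baseline table and visit stream with the statistical
#' structure of the reference trabectome/phaco-trabectome cohort. Per
#' patient: the severity group is drawn from `group_weights`; the index
#' components (baseline IOP bin, medication bin, visual-field stage) are
#' drawn from the component prior conditioned exactly on the assigned group
#' (so the recomputed group always matches); demographics come from the
#' group's multinomial columns; a latent 12-month IOP reduction is drawn
#' from a mean structure linear in severity group with additive covariate
#' effects and a within-group-centered baseline-IOP term; visits follow the
#' configured schedule with the full reduction present from day 1 plus
#' tonometry noise, and medications taper linearly to a group-dependent
#' floor. Surgical failures arising naturally from the trajectories are
#' counted first; additional failures are injected per group to reach the
#' configured 12-month rates, either as sustained pressure elevation at the
#' confirmation pair of visits or as a secondary-surgery flag.
#'
#' @param config A [cohort_config()] object.
#' @return A `gi_cohort` object.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 50, seed = 1))
#' cohort
#' @export
generate_cohort <- function(config) {
  validate_config(unclass(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_patients)
  if (n == 0) {
    return(new_cohort(empty_baseline(), empty_visits(),
                      provenance = list(config = config, seed = config$seed)))
  }
  cal <- generator_calibration(config)
  pid <- sprintf("P%05d", seq_len(n))
  grp <- sample.int(4, n, replace = TRUE, prob = config$group_weights)

  # exact conditional draw over attainable component combinations
  combo_row <- integer(n)
  for (g in 1:4) {
    idx <- which(grp == g)
    if (!length(idx)) next
    d <- which(cal$combos$group == g)
    combo_row[idx] <- sample(d, length(idx), replace = TRUE,
                             prob = cal$combos$prior[d])
  }
  a <- cal$combos$iop_pts[combo_row]
  b <- cal$combos$med_pts[combo_row]
  v <- cal$combos$vf_pts[combo_row]
  base_iop <- iop_bin_lo[a] + sample(0:9, n, replace = TRUE)
  meds <- integer(n)
  meds[b == 1] <- sample(0:1, sum(b == 1), replace = TRUE, prob = c(0.4, 0.6))
  meds[b == 2] <- 2L
  meds[b == 3] <- 3L
  meds[b == 4] <- sample(4:5, sum(b == 4), replace = TRUE,
                         prob = c(0.75, 0.25))
  vf <- gi_levels$vf_stage[v]

  dem <- config$demographics
  baseline <- tibble::tibble(
    patient_id = pid,
    age = as.integer(round(rtrunc_norm(n, config$age_mean[grp],
                                       config$age_sd[grp], 18, 96))),
    gender = sample_levels(dem$gender, grp, n),
    ethnicity = sample_levels(dem$ethnicity, grp, n),
    diagnosis = sample_levels(dem$diagnosis, grp, n),
    lens_status = sample_levels(dem$lens_status, grp, n),
    shaffer_grade = sample_levels(dem$shaffer_grade, grp, n),
    vf_stage = vf,
    cup_disc = round(rtrunc_norm(n, config$cd_mean[grp], config$cd_sd[grp],
                                 0.1, 1.9), 2),
    va_logmar = round(rtrunc_norm(n, config$va_mean[grp], config$va_sd[grp],
                                  -0.19, 3), 2),
    baseline_iop = as.numeric(base_iop),
    baseline_meds = meds,
    surgery = sample_levels(dem$surgery, grp, n)
  )

  eff <- config$covariate_effects
  eff_i <- eff[["hispanic"]] * (baseline$ethnicity == "hispanic") +
    eff[["pseudoexfoliation"]] * (baseline$diagnosis == "pseudoexfoliation") +
    eff[["steroid"]] * (baseline$diagnosis == "steroid") +
    eff[["phaco"]] * (baseline$surgery == "phaco_trabectome")
  reduction <- cal$intercept + config$reduction_per_level * grp + eff_i +
    config$baseline_slope * (base_iop - cal$e_base_iop[grp]) +
    stats::rnorm(n, 0, cal$resid_sd[grp])

  sched <- config$visit_schedule
  nv <- length(sched)
  day <- rep(sched, times = n)
  p_ix <- rep(seq_len(n), each = nv)
  floor_meds <- floor(meds * config$med_floor_frac[grp])
  visits <- tibble::tibble(
    patient_id = pid[p_ix],
    day = day,
    iop = pmax(round(base_iop[p_ix] - reduction[p_ix] +
                       stats::rnorm(n * nv, 0, config$visit_noise_sd), 1), 1),
    meds = as.integer(round(meds[p_ix] - (meds[p_ix] - floor_meds[p_ix]) *
                              pmin(day / 365, 1))),
    secondary_surgery = FALSE
  )

  # top-up failure injection to the configured 12-month rates
  nat <- event_times_internal(baseline$baseline_iop, pid, visits,
                              rule = "confirmed")
  post90 <- sched[sched > 90]
  conf_ok <- which(sched > 90 & dplyr::lag(sched, default = -1) > 90)
  if (length(conf_ok) > 1) conf_ok <- conf_ok[-length(conf_ok)]
  for (g in 1:4) {
    idx <- which(grp == g)
    if (!length(idx)) next
    target <- round(config$failure_rates_12mo[g] * length(idx))
    nat_g <- idx[nat$event[idx]]
    extra <- target - length(nat_g)
    if (extra <= 0) next
    cand <- setdiff(idx, nat_g)
    inject <- if (length(cand) == 1) cand else
      sample(cand, min(extra, length(cand)))
    as_secondary <- stats::runif(length(inject)) < config$p_secondary
    if (length(post90) == 0 || length(conf_ok) == 0) {
      as_secondary[] <- TRUE
    }
    # visits are patient-major: patient i occupies rows (i-1)*nv + 1:nv
    for (i in inject[as_secondary]) {
      d <- if (length(post90) > 1) sample(post90, 1) else post90
      if (length(d) == 0) next
      visits$secondary_surgery[(i - 1) * nv + match(d, sched)] <- TRUE
    }
    for (i in inject[!as_secondary]) {
      j <- if (length(conf_ok) > 1) sample(conf_ok, 1) else conf_ok
      rows <- (i - 1) * nv + c(j - 1, j)
      hi <- max(21.6, 0.82 * baseline$baseline_iop[i])
      visits$iop[rows] <- round(hi + stats::runif(2, 0.2, 1.8), 1)
    }
  }

  new_cohort(baseline, visits,
             provenance = list(config = config, seed = config$seed,
                               assigned_groups = grp))
}
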