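# closed-form normal-equations oracle for OLS
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * xtx_inv)))
}

test_that("12-month reductions are baseline minus follow-up", {
  co <- one_patient_cohort(30, c(30, 365), c(25, 20))
  oc <- compute_outcomes(co, quiet = TRUE)
  expect_identical(oc$iop_reduction_12mo, 10)
  expect_identical(oc$followup_day, 365L)
  expect_identical(attr(oc, "n_excluded"), 0L)
})

test_that("the closest visit to day 365 within the window is used", {
  co <- one_patient_cohort(30, c(300, 420), c(22, 24))
  oc <- compute_outcomes(co, quiet = TRUE)
  expect_identical(oc$followup_day, 420L)
  expect_identical(oc$iop_reduction_12mo, 6)
})

test_that("patients without a qualifying 12-month visit are excluded", {
  bl <- dplyr::bind_rows(make_baseline("P1"), make_baseline("P2"))
  v <- dplyr::bind_rows(make_visits("P1", c(30, 180), c(25, 24)),
                        make_visits("P2", c(30, 365), c(25, 20)))
  co <- new_cohort(bl, v)
  expect_message(oc <- compute_outcomes(co), "1 patient\\(s\\) excluded")
  expect_identical(oc$patient_id, "P2")
  expect_identical(attr(oc, "n_excluded"), 1L)
})

test_that("a noiseless continuous effect is recovered exactly", {
  set.seed(31)
  n <- 40
  ages <- sample(40:90, n, replace = TRUE)
  bl <- make_baseline(patient_id = sprintf("P%02d", 1:n), age = ages,
                      baseline_iop = 30, baseline_meds = 2,
                      vf_stage = "moderate")
  v <- make_visits(bl$patient_id, 365, 30 - 0.2 * ages)
  oc <- compute_outcomes(new_cohort(bl, v), quiet = TRUE)
  # an exact fit makes summary.lm warn about perfect residuals
  scr <- suppressWarnings(univariate_screen(oc, bl, covariates = "age"))
  expect_equal(scr$estimate[scr$term == "age"], 0.2, tolerance = 1e-10)
  expect_lt(scr$p_value[scr$term == "age"], 1e-10)
  expect_true("age" %in% attr(scr, "selected"))
})

test_that("constant covariates are skipped with a warning", {
  co <- generate_cohort(cohort_config(n_patients = 30, seed = 4))
  bl <- co$baseline
  bl$gender <- "female"
  oc <- compute_outcomes(new_cohort(bl, co$visits), quiet = TRUE)
  expect_warning(scr <- univariate_screen(oc, bl,
                                          covariates = c("age", "gender")),
                 "constant")
  expect_false("gender" %in% scr$covariate)
})

test_that("multivariate OLS recovers known additive effects with zero noise", {
  set.seed(77)
  n <- 120
  grp_combo <- list(c(15, 0, "mild"), c(25, 2, "moderate"),
                    c(32, 2, "moderate"), c(45, 4, "end_stage"))
  g <- rep(1:4, length.out = n)
  diag <- sample(c("poag", "steroid"), n, replace = TRUE)
  surg <- sample(c("trabectome_alone", "phaco_trabectome"), n, replace = TRUE)
  bl <- make_baseline(
    patient_id = sprintf("P%03d", 1:n),
    baseline_iop = as.numeric(vapply(grp_combo[g], `[`, "", 1)),
    baseline_meds = as.numeric(vapply(grp_combo[g], `[`, "", 2)),
    vf_stage = vapply(grp_combo[g], `[`, "", 3),
    diagnosis = diag, surgery = surg)
  grp_actual <- score_baseline(bl)$gi_group
  expect_identical(sort(unique(grp_actual)), 1:4)
  red <- 1 + 2 * grp_actual + 3 * (diag == "steroid") - 1.5 *
    (surg == "phaco_trabectome")
  v <- make_visits(bl$patient_id, 365, bl$baseline_iop - red)
  oc <- compute_outcomes(new_cohort(bl, v), quiet = TRUE)
  fit <- suppressWarnings(multivariate_fit(oc, bl, covariates = "diagnosis"))
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est["gi_group"]), 2, tolerance = 1e-9)
  expect_equal(unname(est["diagnosissteroid"]), 3, tolerance = 1e-9)
  expect_equal(unname(est["surgeryphaco_trabectome"]), -1.5,
               tolerance = 1e-9)
  expect_equal(unname(est["(Intercept)"]), 1, tolerance = 1e-9)
})

test_that("OLS estimates equal the normal-equations solution", {
  co <- default_sim(n = 5000, seed = 42)
  oc <- compute_outcomes(co, quiet = TRUE)
  sub_ids <- co$baseline$patient_id[1:60]
  bl <- co$baseline[co$baseline$patient_id %in% sub_ids, ]
  ocs <- oc[oc$patient_id %in% sub_ids, ]
  fit <- multivariate_fit(ocs, bl, covariates = character(),
                          always_include = c("gi_group", "surgery"))
  sc <- score_baseline(bl)
  X <- cbind(1, sc$gi_group[match(ocs$patient_id, sc$patient_id)],
             as.numeric(sc$surgery[match(ocs$patient_id, sc$patient_id)] ==
                          "phaco_trabectome"))
  o <- oracle_ols(X, ocs$iop_reduction_12mo)
  expect_equal(unname(fit$estimate), unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(fit$std_error), unname(o$se), tolerance = 1e-10)
})

test_that("univariate and multivariate coincide for orthogonal covariates", {
  # balanced crossing of severity group and surgery: orthogonal design
  grp_combo <- list(c(15, 0, "mild"), c(25, 2, "moderate"),
                    c(32, 3, "advanced"), c(45, 4, "end_stage"))
  g <- rep(1:4, each = 10)
  surg <- rep(rep(c("trabectome_alone", "phaco_trabectome"), each = 5), 4)
  bl <- make_baseline(
    patient_id = sprintf("P%03d", seq_along(g)),
    baseline_iop = as.numeric(vapply(grp_combo[g], `[`, "", 1)),
    baseline_meds = as.numeric(vapply(grp_combo[g], `[`, "", 2)),
    vf_stage = vapply(grp_combo[g], `[`, "", 3),
    surgery = surg)
  set.seed(55)
  red <- round(rnorm(length(g), 5, 2), 1)
  v <- make_visits(bl$patient_id, 365, pmax(bl$baseline_iop - red, 1))
  oc <- compute_outcomes(new_cohort(bl, v), quiet = TRUE)
  scr <- univariate_screen(oc, bl, covariates = "surgery")
  fit <- multivariate_fit(oc, bl, covariates = character())
  expect_equal(fit$estimate[fit$term == "surgeryphaco_trabectome"],
               scr$estimate[scr$term == "surgeryphaco_trabectome"],
               tolerance = 1e-10)
})

test_that("a rank-deficient design is reported with the collinear term", {
  bl <- make_baseline(patient_id = sprintf("P%d", 1:12),
                      baseline_iop = rep(c(15, 25, 32, 45), 3),
                      baseline_meds = rep(c(0, 2, 3, 4), 3),
                      vf_stage = rep(c("mild", "moderate", "advanced",
                                       "end_stage"), 3),
                      ethnicity = rep(c("african_american", "hispanic"), 6),
                      surgery = rep(c("trabectome_alone",
                                      "phaco_trabectome"), 6))
  v <- make_visits(bl$patient_id, 365, bl$baseline_iop - 5)
  oc <- compute_outcomes(new_cohort(bl, v), quiet = TRUE)
  expect_error(multivariate_fit(oc, bl, covariates = "ethnicity"),
               "rank deficient.*ethnicityhispanic|rank deficient.*surgery")
})

test_that("visit trajectory summaries aggregate by group and day", {
  co <- generate_cohort(cohort_config(n_patients = 200, seed = 8))
  tr <- summarize_visits(co)
  sched <- cohort_config()$visit_schedule
  expect_true(all(tr$day %in% sched))
  expect_identical(sum(tr$n), nrow(co$visits))
  # pressure at one year sits below the day-1 value in every group
  d1 <- tr[tr$day == 1, ]
  d365 <- tr[tr$day == 365, ]
  expect_true(all(d365$iop_mean < d1$iop_mean + 1))
})
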