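# hand product-limit oracle: S(t) over sorted unique event times, failures
# before censorings at ties
oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event]))) {
    if (t > at) break
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_at_risk)
  }
  s
}

# hand two-group log-rank oracle: observed-minus-expected failures with
# hypergeometric variance over pooled event times
oracle_logrank2 <- function(time, event, group) {
  gs <- sort(unique(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == gs[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == gs[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("failure requires two consecutive failing visits after day 90", {
  co <- one_patient_cohort(30, c(30, 120, 180), c(20, 28, 27))
  ev <- classify_events(co)
  expect_true(ev$event)
  expect_identical(ev$time, 180)
  expect_identical(ev$cause, "iop_criterion")

  # alternating success/failure never confirms
  co2 <- one_patient_cohort(30, c(120, 180, 270, 365), c(28, 20, 28, 20))
  ev2 <- classify_events(co2)
  expect_false(ev2$event)
  expect_identical(ev2$cause, "censored")
  expect_identical(ev2$time, 365)

  # visits before day 90 never count
  co3 <- one_patient_cohort(30, c(60, 120, 180, 365), c(29, 20, 21, 20))
  ev3 <- classify_events(co3)
  expect_false(ev3$event)

  # the first visit after day 90 cannot confirm against a pre-90 partner
  co4 <- one_patient_cohort(30, c(80, 120, 365), c(28, 28, 20))
  expect_false(classify_events(co4)$event)
})

test_that("secondary surgery fails the patient regardless of pressure", {
  co <- one_patient_cohort(30, c(120, 200, 365), c(15, 15, 15),
                           secondary = c(FALSE, TRUE, FALSE))
  ev <- classify_events(co)
  expect_true(ev$event)
  expect_identical(ev$time, 200)
  expect_identical(ev$cause, "secondary_surgery")
})

test_that("the single-visit rule fails at the first qualifying visit", {
  co <- one_patient_cohort(30, c(120, 180), c(28, 20))
  expect_false(classify_events(co, rule = "confirmed")$event)
  ev <- classify_events(co, rule = "single_visit")
  expect_true(ev$event)
  expect_identical(ev$time, 120)
})

test_that("trailing visits after a failure do not change the event", {
  co <- one_patient_cohort(30, c(120, 180), c(28, 27))
  ev <- classify_events(co)
  co2 <- one_patient_cohort(30, c(120, 180, 270, 365), c(28, 27, 15, 15))
  ev2 <- classify_events(co2)
  expect_identical(ev$time, ev2$time)
  expect_identical(ev$cause, ev2$cause)
})

test_that("censoring is capped at day 365 for the 12-month analysis", {
  co <- one_patient_cohort(30, c(120, 400), c(20, 20))
  expect_identical(classify_events(co)$time, 365)
  expect_identical(classify_events(co, cap_day = NULL)$time, 400)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  ev <- tibble::tibble(time = c(100, 200, 365), event = c(TRUE, TRUE, FALSE),
                       gi_group = 1L)
  km <- km_estimate(ev)
  expect_equal(km$s_12mo$s_12mo, (1 - 1 / 3) * (1 - 1 / 2))
  expect_equal(km$s_12mo$s_12mo, 1 / 3)

  # no failures: survival stays at 1
  ev0 <- tibble::tibble(time = c(100, 365), event = FALSE, gi_group = 2L)
  expect_equal(km_estimate(ev0)$s_12mo$s_12mo, 1)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(404)
  for (i in 1:5) {
    times <- sample(30:400, 8)
    ev <- tibble::tibble(time = times, event = TRUE, gi_group = 1L)
    km <- km_estimate(ev)
    cv <- km$curves
    for (j in seq_len(nrow(cv))) {
      expect_equal(cv$survival[j], mean(times > cv$time[j]))
    }
  }
})

test_that("delaying a censoring past the last event leaves survival unchanged", {
  ev <- tibble::tibble(time = c(100, 200, 300), event = c(TRUE, TRUE, FALSE),
                       gi_group = 1L)
  ev_late <- ev
  ev_late$time[3] <- 364
  km1 <- km_estimate(ev)
  km2 <- km_estimate(ev_late)
  at_events <- km1$curves[km1$curves$n_event > 0, c("time", "survival")]
  at_events2 <- km2$curves[km2$curves$n_event > 0, c("time", "survival")]
  expect_equal(at_events, at_events2)
  expect_equal(km1$s_12mo$s_12mo, km2$s_12mo$s_12mo)
})

test_that("log-rank matches the brute-force two-group computation", {
  set.seed(505)
  for (i in 1:6) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:5, 1)
    time <- c(sample(50:400, n1), sample(50:400, n2))
    event <- runif(n1 + n2) < 0.8
    if (!any(event)) event[1] <- TRUE
    group <- rep(1:2, c(n1, n2))
    lr <- log_rank(tibble::tibble(time = time, event = event,
                                  gi_group = group))
    expect_equal(lr$statistic, oracle_logrank2(time, event, group),
                 tolerance = 1e-10)
    expect_identical(lr$df, 1L)
    # symmetric under group relabeling
    lr_swap <- log_rank(tibble::tibble(time = time, event = event,
                                       gi_group = 3 - group))
    expect_equal(lr_swap$statistic, lr$statistic, tolerance = 1e-12)
  }
})

test_that("log-rank degenerate inputs are handled", {
  ev <- tibble::tibble(time = rep(c(100, 200), 2),
                       event = rep(c(TRUE, TRUE), 2),
                       gi_group = rep(1:2, each = 2))
  lr <- log_rank(ev)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  expect_error(log_rank(tibble::tibble(time = 100, event = FALSE,
                                       gi_group = 1L)),
               "at least 2 groups")
  expect_error(log_rank(tibble::tibble(time = c(100, 100),
                                       event = FALSE,
                                       gi_group = c(1L, 2L))),
               "censored")
})
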