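# Kaplan-Meier, exponential Greenwood bands, Cox regression, reverse analysis.

test_that("KM reproduces the hand-worked five-patient example", {
  # five patients, deaths at months 2 and 4, the rest event-free later
  km <- km_estimate(c(2, 4, 6, 8, 10), c(1, 1, 1, 1, 1))
  expect_equal(km_survival_at(km, 2), 0.8)
  expect_equal(km_survival_at(km, 4), 0.6)
  expect_equal(km_survival_at(km, 1.9), 1)
  # all censored -> survival identically 1
  km0 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_equal(km_survival_at(km0, c(1, 5, 100)), c(1, 1, 1))
  # duplicating every patient leaves the estimate unchanged
  km2 <- km_estimate(rep(c(2, 4, 6, 8, 10), 2), rep(1, 10))
  expect_equal(km2$survival, km_estimate(c(2, 4, 6, 8, 10), rep(1, 5))$survival)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring equals one minus the ECDF of event times", {
  set.seed(6)
  t0 <- rexp(40, 0.1)
  km <- km_estimate(t0, rep(1, 40))
  grid <- seq(0.5, 30, by = 0.5)
  expect_equal(km_survival_at(km, grid), 1 - stats::ecdf(t0)(grid))
})

test_that("exponential Greenwood band equals the closed form and stays in [0,1]", {
  times <- c(2, 4, 6, 8, 10); events <- rep(1, 5)
  km <- greenwood_ci(km_estimate(times, events))
  # at t = 2: S = 0.8, chat = 1/(5*4) = 1/20
  chat <- 1 / 20
  v <- chat / log(0.8)^2
  z <- stats::qnorm(0.975)
  expect_equal(km$ci_lower[1], 0.8^exp(z * sqrt(v)), tolerance = 1e-12)
  expect_equal(km$ci_upper[1], 0.8^exp(-z * sqrt(v)), tolerance = 1e-12)
  expect_true(km$ci_lower[1] < 0.8 && 0.8 < km$ci_upper[1])
  expect_true(all(km$ci_lower[1] > 0 & km$ci_upper[1] < 1))
  # S = 0 at the last event time: band omitted there
  expect_true(is.na(km$ci_lower[5]) && is.na(km$ci_upper[5]))
  # bands always inside [0,1] on random cohorts
  for (seed in 1:5) {
    co <- random_cohort(30, seed = 300 + seed)
    k <- greenwood_ci(km_estimate(co$time_months, co$event))
    ok <- !is.na(k$ci_lower)
    expect_true(all(k$ci_lower[ok] >= 0 & k$ci_upper[ok] <= 1))
    expect_true(all(k$ci_lower[ok] <= k$survival[ok] + 1e-12))
    expect_true(all(k$ci_upper[ok] >= k$survival[ok] - 1e-12))
  }
  expect_error(greenwood_ci(km_estimate(c(1, 2), c(1, 0)), alpha = 1.5),
               "config error")
})

test_that("KM and bands agree with survival::survfit log-log intervals", {
  skip_if_not_installed("survival")
  co <- random_cohort(25, seed = 77)
  km <- greenwood_ci(km_estimate(co$time_months, co$event))
  sf <- survival::survfit(survival::Surv(co$time_months, co$event) ~ 1,
                          conf.type = "log-log")
  sm <- summary(sf, times = km$event_times)
  expect_equal(km$survival, sm$surv, tolerance = 1e-10)
  ok <- !is.na(km$ci_lower)
  expect_equal(km$ci_lower[ok], sm$lower[ok], tolerance = 1e-8)
  expect_equal(km$ci_upper[ok], sm$upper[ok], tolerance = 1e-8)
})

test_that("Cox fit matches a grid-search oracle and the survival package", {
  times <- c(2, 3, 5, 7, 8, 11, 14, 17, 21, 28)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  x <- c(1.2, 0.8, 0.3, 0.9, 0.1, 0.7, 0.2, 0.4, 0.05, 0.1)
  fit <- cox_fit(x, times, events)
  grid <- seq(fit$beta - 0.3, fit$beta + 0.3, by = 1e-5)
  ll <- vapply(grid, spectrosurv:::cox_partial_loglik, numeric(1),
               covariate = x, times = times, events = events)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-4)

  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(times, events) ~ x,
                         ties = "breslow")
  expect_equal(fit$beta, unname(ref$coefficients), tolerance = 1e-6)
  expect_equal(fit$standard_error, sqrt(unname(ref$var[1, 1])),
               tolerance = 1e-6)
})

test_that("Cox null and parameter-recovery behaviour", {
  set.seed(8)
  # covariate independent of survival: beta within 3 SE of zero
  n <- 200
  t0 <- rexp(n, 0.1); x <- rnorm(n)
  fit0 <- cox_fit(x, t0, rep(1, n))
  expect_lt(abs(fit0$beta) / fit0$standard_error, 3)
  # binary covariate, true HR 4, no censoring
  x1 <- rep(c(0, 1), each = 250)
  t1 <- rexp(500, 0.05 * 4^x1)
  fit1 <- cox_fit(x1, t1, rep(1, 500))
  expect_gt(fit1$hazard_ratio, 3.2)
  expect_lt(fit1$hazard_ratio, 5.0)
  expect_true(fit1$ci_lower < fit1$hazard_ratio &
              fit1$hazard_ratio < fit1$ci_upper)
  expect_error(cox_fit(rep(1, 5), c(1, 2, 3, 4, 5), rep(1, 5)), "constant")
  expect_error(cox_fit(c(1, 2), c(1, 2), c(0, 0)), "event")
})

test_that("Cox flags monotone likelihoods instead of diverging", {
  # perfect separation: the largest covariates die first
  times <- c(1, 2, 3, 10, 20, 30)
  events <- c(1, 1, 1, 0, 0, 0)
  x <- c(5, 4, 3, 0.1, 0.2, 0.3)
  expect_warning(fit <- cox_fit(x, times, events), "monotone")
  expect_true(fit$separation)
  expect_true(is.finite(fit$beta))
})

test_that("reverse analysis maximises the log-rank over score thresholds", {
  co <- make_cohort(c(2, 3, 4, 30, 35, 40, 45, 50, 55, 60),
                    c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))
  # scores perfectly ordered by outcome class (3 high-risk, 7 low-risk)
  sc <- stats::setNames(c(.9, .85, .8, .3, .25, .2, .15, .1, .05, .02),
                        co$patient_id)
  out <- reverse_analysis(sc, co, min_group_size = 3)
  expect_equal(unname(out$groups[1:3]), rep("high", 3))
  expect_equal(unname(out$groups[4:10]), rep("low", 7))
  expect_gt(out$threshold, 0.3); expect_lt(out$threshold, 0.8)
  # statistic equals the plain two-class log-rank at that split
  direct <- logrank(co$time_months, co$event,
                    ifelse(sc >= out$threshold, "high", "low"))
  expect_equal(out$logrank$statistic, direct$statistic)
  # exhaustive check: no candidate beats the returned one
  su <- sort(unique(sc)); cand <- (su[-1] + su[-length(su)]) / 2
  stats_all <- vapply(cand, function(th) {
    g <- ifelse(sc >= th, "h", "l")
    if (min(table(g)) < 3) return(-Inf)
    logrank(co$time_months, co$event, g)$statistic
  }, numeric(1))
  expect_equal(out$logrank$statistic, max(stats_all))
  expect_true(all(!is.na(out$km_high$survival)))
  expect_error(reverse_analysis(stats::setNames(rep(0.5, 10), co$patient_id), co),
               "degenerate")
})
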