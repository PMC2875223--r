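test_that("cumulative intensities vanish without terminal mutations", {
  p <- small_params(alpha = c(2e-3, 5e-3, 0), beta = c(1e-3, 2e-3, 4e-3, 0))
  om <- cumulative_intensity(p, c(50, 150, 300))
  expect_true(all(om == 0))
})

test_that("cumulative intensities are nondecreasing in time", {
  set.seed(502)
  for (i in 1:4) {
    p <- draw_prior_params(with_decay = TRUE)
    om <- cumulative_intensity(p, seq(0, 240, by = 24))
    expect_true(all(diff(om[, 1]) >= 0))
    expect_true(all(diff(om[, 2]) >= 0))
  }
})

test_that("cumulative intensity matches a fine trapezoid quadrature oracle", {
  p <- small_params()           # time-homogeneous: closed form available
  t_eval <- c(100, 200)
  om <- cumulative_intensity(p, t_eval, engine = "ode")
  # independently coded quadrature of the lagged integrand
  for (k in seq_along(t_eval)) {
    s <- seq(0, t_eval[k] - p$detect_lag, by = 0.004)
    u <- expected_numbers(p, s)
    o1 <- sum(diff(s) * (head(p$alpha[3] * u$uI[, 3], -1) +
                           tail(p$alpha[3] * u$uI[, 3], -1)) / 2)
    o2 <- sum(diff(s) * (head(p$beta[4] * u$uJ[, 4], -1) +
                           tail(p$beta[4] * u$uJ[, 4], -1)) / 2)
    expect_lt(abs(om[k, 1] - o1) / o1, 1e-8)
    expect_lt(abs(om[k, 2] - o2) / o2, 1e-8)
  }
})

test_that("pathway probabilities combine by inclusion-exclusion", {
  sched <- small_schedule()
  # one pathway switched off: the total equals the other pathway exactly
  p1 <- small_params(alpha = c(2e-3, 5e-3, 0))
  risk1 <- age_group_probabilities(p1, sched)
  expect_equal(risk1$Q1, rep(0, 4))
  expect_equal(risk1$QT, risk1$Q2)
  # inclusion-exclusion bound on the additive approximation, random draws
  set.seed(503)
  for (i in 1:10) {
    p <- draw_prior_params(with_decay = TRUE)
    risk <- age_group_probabilities(p, sched, engine = "grid")
    expect_true(all(risk$Q1 >= 0 & risk$Q1 <= 1))
    expect_true(all(risk$QT <= 1))
    expect_true(all(abs(risk$QT - risk$QT_additive) <=
                      risk$Q1 * risk$Q2 + 1e-15))
    expect_true(all(risk$QT >= pmax(risk$Q1, risk$Q2) - 1e-15))
  }
})

test_that("lifetime first-onset probabilities sum to at most one per pathway", {
  p <- default_params()
  sched <- data.frame(age_lo = seq(0, 95, 5), age_hi = seq(5, 100, 5))
  risk <- age_group_probabilities(p, sched)
  expect_lte(sum(risk$Q1), 1)
  expect_lte(sum(risk$Q2), 1)
  # the sums telescope to 1 - survivor at the grid end
  om <- cumulative_intensity(p, colonmsce::years_to_units(100, p))
  expect_equal(sum(risk$Q1), unname(1 - exp(-om[1, 1])), tolerance = 1e-10)
})

test_that("expected cases scale linearly in the population at risk", {
  p <- small_params()
  sched <- small_schedule()
  tab <- incidence_table(sched$age_lo, sched$age_hi, sched$n, rep(0, 4))
  tau <- expected_cases(p, tab)
  tab2 <- tab; tab2$n <- 2 * tab2$n
  expect_equal(expected_cases(p, tab2), 2 * tau, tolerance = 1e-12)
  expect_equal(expected_cases(null_params(), tab), rep(0, 4))
})

test_that("poisson log-likelihood matches the dpois oracle", {
  expect_equal(poisson_loglik(1, 1), -1)
  expect_equal(poisson_loglik(numeric(0), numeric(0)), 0)
  set.seed(504)
  y <- rpois(10, 40)
  tau <- 40 * runif(10, 0.6, 1.4)
  expect_equal(poisson_loglik(y, tau), sum(dpois(y, tau, log = TRUE)),
               tolerance = 1e-12)
  expect_warning(ll <- poisson_loglik(c(0, 3), c(2, 0)), "-Inf")
  expect_identical(ll, -Inf)
})

test_that("deviance is the saturated log-likelihood-ratio statistic", {
  # saturated model: zero deviance
  expect_equal(poisson_deviance(c(4, 9), c(4, 9)), 0)
  # toy case against an independently coded likelihood-ratio oracle
  y <- c(10, 20); tau <- c(12, 18)
  oracle <- 2 * (sum(dpois(y, y, log = TRUE)) - sum(dpois(y, tau, log = TRUE)))
  expect_equal(poisson_deviance(y, tau), oracle, tolerance = 1e-12)
  # positivity away from saturation and invariance to group order
  set.seed(505)
  y <- rpois(8, 100); tau <- y * runif(8, 0.8, 1.25)
  expect_gt(poisson_deviance(y, tau), 0)
  o <- sample(8)
  expect_equal(poisson_deviance(y[o], tau[o]), poisson_deviance(y, tau))
  # zero-count groups contribute 2 * tau (continuity limit)
  expect_equal(poisson_deviance(0, 3.5), 7)
})

test_that("information criteria follow their arithmetic definitions", {
  ic0 <- information_criteria(0, 0, 18)
  expect_equal(ic0$AIC, 0)
  expect_equal(ic0$BIC, 0)
  ic <- information_criteria(30, 13, 18)
  expect_equal(ic$AIC, 56)
  expect_equal(ic$BIC, 30 + 13 * log(18))
  expect_equal(ic$p, 13)
  expect_equal(ic$n_points, 18)
})

test_that("time-to-tumour density integrates to one minus the survivor", {
  p <- default_params()
  ages <- seq(0, 90, by = 0.25)
  dens <- time_to_tumor_density(p, ages)
  expect_true(all(dens$density >= 0))
  total <- sum(diff(ages) * (head(dens$density, -1) + tail(dens$density, -1)) / 2)
  expect_lte(total, 1)
  expect_equal(total, 1 - dens$survivor[length(ages)], tolerance = 2e-3)
  # no initiation, no density
  expect_true(all(time_to_tumor_density(null_params(), c(0, 40, 80))$density == 0))
})
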