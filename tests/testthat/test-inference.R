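make_stats <- function(...) {
  base <- list(M0_I = 1400, M0_J = 830, M_I = c(100, 50), M_J = c(40, 30, 20),
               B = c(I2 = 74, I3 = 50, J3 = 40, J4 = 60),
               D = c(I2 = 38, I3 = 20, J3 = 25, J4 = 15),
               expo_I = c(1e6, 1e4, 5e3), expo_J = c(1e6, 1e5, 1e4, 5e3),
               expo_decay = c(I2 = 1e4, J3 = 1e4),
               steps = 10, cohort_size = 1)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  structure(list(K = 1, cohort_size = base$cohort_size, weights = 1,
                 log_weights = 0, ess = 1, selected = 1,
                 selected_stats = base, horizon = 10),
            class = "colon_latents")
}

test_that("the prior box is open, contains the published estimates", {
  pr <- default_prior()
  expect_identical(log_prior(default_params(), pr), 0)
  # outside the box in one coordinate
  p_out <- set_param_vector(default_params(), c(gamma_I3 = 0.6))
  expect_identical(log_prior(p_out, pr), -Inf)
  # boundary values count as outside (open intervals)
  p_edge <- set_param_vector(default_params(), c(alpha3 = pr$alpha3[1]))
  expect_identical(log_prior(p_edge, pr), -Inf)
})

test_that("weighted bootstrap resampling follows the weights", {
  set.seed(601)
  # equal weights: indistinguishable from uniform (chi-square GOF)
  draws <- colonmsce:::resample_index(rep(0.2, 5), 1e4)
  gof <- suppressWarnings(chisq.test(tabulate(draws, 5)))
  expect_gt(gof$p.value, 0.01)
  # 0.9 / 0.1 weights: selection frequency within 3 binomial SE
  draws2 <- colonmsce:::resample_index(c(0.9, 0.1), 1e4)
  se <- sqrt(0.9 * 0.1 / 1e4)
  expect_lt(abs(mean(draws2 == 1) - 0.9), 3 * se)
})

test_that("augmentation returns a single path unchanged when K = 1", {
  p <- default_params()
  tab <- seer_colon_table()
  lat <- augment_latents(p, tab, K = 1, cohort_size = 50, seed = 5)
  expect_equal(lat$selected, 1L)
  expect_equal(lat$weights, 1)
  expect_equal(lat$ess, 1)
  expect_equal(lat$selected_stats$cohort_size, 50)
})

test_that("augmentation weights favour paths matching the observations", {
  p <- default_params()
  tab <- seer_colon_table()
  lat <- augment_latents(p, tab, K = 6, cohort_size = 100, seed = 6)
  expect_length(lat$weights, 6)
  expect_equal(sum(lat$weights), 1)
  expect_gte(lat$ess, 1)
  expect_lte(lat$ess, 6)
  expect_equal(lat$selected, which.max(lat$weights))  # degenerate weights
})

test_that("latent-count conditional modes equal events over exposure", {
  pr <- default_prior()
  p <- default_params()
  th <- conditional_update_theta1(make_stats(), pr, p)
  v <- param_vector(th)
  # Poisson-count parameters: mode = count / exposure (box-interior cases)
  expect_equal(v[["alpha1"]], 100 / 1e6, tolerance = 1e-9)
  expect_equal(v[["lambda_I"]], 140, tolerance = 1e-9)
  # independent 1-D grid maximisation of the conditional log-density
  grid <- exp(seq(log(1e-8), log(1e-2), length.out = 20001))
  dens <- 100 * log(grid) - grid * 1e6
  expect_equal(v[["alpha1"]], grid[which.max(dens)], tolerance = 1e-3)
  # multinomial birth/death mode
  expect_equal(v[["b_I2"]], 7.4e-3, tolerance = 1e-9)
  expect_equal(v[["gamma_I2"]], 7.4e-3 - 3.8e-3, tolerance = 1e-9)
})

test_that("zero-count and zero-exposure latent updates behave as documented", {
  pr <- default_prior()
  p <- default_params()
  # zero events over positive exposure: truncated mode at the lower bound
  th <- conditional_update_theta1(make_stats(M_I = c(0, 50)), pr, p)
  expect_lt(param_vector(th)[["alpha1"]], pr$alpha1[1] * 1.01)
  # zero exposure: the update is skipped and reported
  th2 <- conditional_update_theta1(make_stats(expo_I = c(0, 1e4, 5e3)), pr, p)
  expect_equal(param_vector(th2)[["alpha1"]], p$alpha[1])
  expect_true("alpha1" %in% attr(th2, "skipped"))
})

test_that("terminal mutation rates are driven to the floor by empty data", {
  p <- default_params()
  tab <- seer_colon_table()
  tab$y <- rep(0, nrow(tab))
  out <- conditional_update_theta2(p, tab, maxit = 60)
  v <- param_vector(out$params)
  pr <- default_prior()
  expect_lt(v[["alpha3"]], pr$alpha3[1] * 1.05)
  expect_lt(v[["beta4"]], pr$beta4[1] * 1.05)
})

test_that("terminal mutation rates are recovered from synthetic data", {
  truth <- set_param_vector(default_params(),
                            c(alpha3 = 6e-7, beta4 = 3e-6))
  tab <- seer_colon_table()
  tab$y <- round(expected_cases(truth, tab, engine = "grid"))
  start <- set_param_vector(truth, c(alpha3 = 1e-5, beta4 = 1e-5))
  out <- conditional_update_theta2(start, tab, maxit = 200)
  v <- param_vector(out$params)
  expect_lt(abs(v[["alpha3"]] / 6e-7 - 1), 0.10)
  expect_lt(abs(v[["beta4"]] / 3e-6 - 1), 0.10)
})

test_that("the terminal-rate conditional is unimodal along each coordinate", {
  p <- default_params()
  tab <- seer_colon_table()
  tab$y <- round(expected_cases(p, tab, engine = "grid"))
  # scanned up to 1e-4: beyond that the onset probabilities saturate (nearly
  # everyone is affected early) and the likelihood enters a separate
  # degenerate regime
  for (nm in c("alpha3", "beta4")) {
    grid <- exp(seq(log(1e-8), log(1e-4), length.out = 41))
    nll <- vapply(grid, function(x) {
      q <- set_param_vector(p, stats::setNames(x, nm))
      colonmsce:::incidence_nll(q, tab, engine = "grid")
    }, numeric(1))
    d <- diff(nll)
    d <- d[abs(d) > 1e-7 * max(abs(nll))]   # ignore flat-region jitter
    sign_changes <- sum(diff(sign(d)) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("expected cases depend on last-stage rates only through b - d", {
  p <- default_params()
  tab <- seer_colon_table()
  tau0 <- expected_cases(p, tab)
  shift <- 2e-3
  q <- p
  q$b_I[3] <- q$b_I[3] + shift; q$d_I[3] <- q$d_I[3] + shift
  q$b_J[4] <- q$b_J[4] + shift; q$d_J[4] <- q$d_J[4] + shift
  tau1 <- expected_cases(q, tab)
  expect_lt(max(abs(tau1 - tau0) / pmax(tau0, 1e-12)), 1e-10)
})

test_that("growth-block updates improve the observation likelihood", {
  p <- default_params()
  tab <- seer_colon_table()
  before <- colonmsce:::incidence_nll(p, tab, engine = "grid")
  out <- conditional_update_growth(p, tab, maxit = 30)
  expect_lte(out$value, before)
})

test_that("the Gibbs fit is reproducible and honours the prior box", {
  tab <- seer_colon_table()
  cfg <- fit_config(n_burnin = 2, n_draws = 3, n_chains = 2, K = 3,
                    cohort_size = 100, optim_maxit = 6)
  f1 <- gibbs_fit(tab, config = cfg, seed = 11)
  f2 <- gibbs_fit(tab, config = cfg, seed = 11)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$draws, f2$draws)
  # every retained draw lies inside the (closed) prior box
  pr <- default_prior()
  for (nm in names(pr)) {
    expect_true(all(f1$draws[, nm] >= pr[[nm]][1] - 1e-12))
    expect_true(all(f1$draws[, nm] <= pr[[nm]][2] + 1e-12))
  }
  # draws are pooled over the chains that reached the best posterior region
  expect_equal(nrow(f1$draws), 3 * length(f1$chains_pooled))
})

test_that("prediction refuses a non-converged fit unless forced", {
  tab <- seer_colon_table()
  cfg <- fit_config(n_burnin = 1, n_draws = 2, n_chains = 1, K = 2,
                    cohort_size = 100, optim_maxit = 4)
  fit <- gibbs_fit(tab, config = cfg, seed = 3)
  expect_false(fit$converged)   # far too few cycles to stabilise
  expect_error(predict_incidence(fit), "converge")
  pred <- predict_incidence(fit, force = TRUE)
  expect_equal(pred$predicted,
               expected_cases(fit$params_hat, tab,
                              engine = fit$config$engine))
  expect_true(all(pred$lower <= pred$upper))
})
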