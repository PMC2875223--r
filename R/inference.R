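# Generalized-Bayesian fitting by multi-level Gibbs sampling.
#
# The procedure alternates three steps until the parameter mode stabilises:
#
#   Step 1 (data augmentation): simulate K candidate latent paths (X, U) of
#     the stochastic system at the current parameters and select among them
#     by the weighted bootstrap, with weights proportional to the Poisson
#     observation likelihood P{Y = y | X, U, Theta} evaluated at the
#     path-realised onset probabilities.  Paths are simulated at the
#     representative-individual (cohort) level: the weights depend on the
#     latent path only through the expected case counts tau, so per-person
#     resolution across tens of millions at risk adds nothing.
#
#   Step 2 (conditional modes): update the parameter blocks in a fixed
#     order.  (i) Initiation and non-terminal mutation rates have
#     Gamma-shaped conditionals given the latent counts; their truncated
#     modes are event-count / exposure projected into the prior box, and the
#     birth/death pairs of the proliferating stages have multinomial-mode
#     updates.  (ii) The proliferation / growth-limiting block and (iii) the
#     terminal mutation rates (alpha_3, beta_4) enter the observation layer
#     through the expected-number onset probabilities, so their conditional
#     posteriors are maximised numerically (bounded quasi-Newton inside the
#     log prior box).
#
#   Step 3 (recycling): feed the updated parameters back into Step 1.
#
# After convergence the per-cycle modes are collected as posterior draws;
# the reported estimates are their sample means.

#' Data-augmentation step: weighted bootstrap over candidate latent paths
#'
#' Simulates `K` candidate latent trajectories (staging and transition
#' variables) of the stochastic system under `params`, weights each by the
#' Poisson observation likelihood of the table at the path-realised expected
#' case counts, and resamples one path with probability proportional to the
#' weights (sampling importance resampling).
#'
#' @param params a [colon_params()] object.
#' @param table an [incidence_table()].
#' @param K number of candidate paths (`K >= 1`).
#' @param cohort_size persons represented by one latent path.  Initiation is
#'   linear in the person count, so a cohort path is the same branching
#'   system with `lambda` scaled up; per-person onset intensities are
#'   recovered by dividing by the cohort size.  Cohort-level paths keep the
#'   latent event counts large enough that the conditional-mode updates are
#'   well determined.
#' @param seed optional integer seed.
#' @return A `colon_latents` list: per-path sufficient statistics, log
#'   weights, normalised `weights`, effective sample size `ess`, the
#'   `selected` index and its `selected_stats`.
#' @export
augment_latents <- function(params, table, K, cohort_size = 200,
                            seed = NULL) {
  stopifnot(K >= 1, cohort_size >= 1)
  table <- validate_incidence_table(as.data.frame(table))
  horizon <- as.integer(ceiling(years_to_units(max(table$age_hi), params)))
  params_c <- params
  params_c$lambda_I <- params$lambda_I * cohort_size
  params_c$lambda_J <- params$lambda_J * cohort_size
  sim <- simulate_cohort(params_c, horizon, K, omega_paths = TRUE,
                         stats = TRUE, seed = seed)
  sim$omega_path1 <- sim$omega_path1 / cohort_size
  sim$omega_path2 <- sim$omega_path2 / cohort_size
  lo <- as.integer(round(years_to_units(table$age_lo, params)))
  hi <- as.integer(round(years_to_units(table$age_hi, params)))
  om1_lo <- sim$omega_path1[, lo + 1L, drop = FALSE]
  om1_hi <- sim$omega_path1[, hi + 1L, drop = FALSE]
  om2_lo <- sim$omega_path2[, lo + 1L, drop = FALSE]
  om2_hi <- sim$omega_path2[, hi + 1L, drop = FALSE]
  Q1 <- exp(-om1_lo) - exp(-om1_hi)
  Q2 <- exp(-om2_lo) - exp(-om2_hi)
  QT <- Q1 + Q2 - Q1 * Q2
  log_w <- vapply(seq_len(K), function(k) {
    tau <- pmax(table$n * QT[k, ], 1e-300)  # zero-mass groups: constant floor
    sum(table$y * log(tau) - tau - lgamma(table$y + 1))
  }, numeric(1))
  if (all(!is.finite(log_w)))
    stop("all augmentation weights are zero; increase K or improve the ",
         "current parameters", call. = FALSE)
  w <- exp(log_w - max(log_w[is.finite(log_w)]))
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  selected <- resample_index(w, 1L)
  stat_of <- function(k) {
    s <- sim$stats
    list(M0_I = s$M0[k, 1], M0_J = s$M0[k, 2],
         M_I = s$M_I[k, ], M_J = s$M_J[k, ],
         B = s$B[k, ], D = s$D[k, ],
         expo_I = s$expo_I[k, ], expo_J = s$expo_J[k, ],
         expo_decay = s$expo_decay[k, ], steps = s$steps,
         cohort_size = cohort_size)
  }
  structure(list(K = K, cohort_size = cohort_size,
                 weights = w, log_weights = log_w, ess = ess,
                 selected = selected, selected_stats = stat_of(selected),
                 horizon = horizon),
            class = "colon_latents")
}

# weighted resampling with replacement (importance resampling kernel)
resample_index <- function(w, n) {
  sample.int(length(w), size = n, replace = TRUE, prob = w)
}

#' @export
print.colon_latents <- function(x, ...) {
  cat(sprintf("Augmented latent paths: K = %d, ESS = %.2f, selected = %d\n",
              x$K, x$ess, x$selected))
  invisible(x)
}

#' Conditional-mode update of the latent-count parameter block
#'
#' Given a selected latent path, the initiation intensities and the
#' non-terminal mutation rates have Gamma-shaped conditional posteriors
#' whose (box-truncated) modes are total events divided by total exposure;
#' the birth/death pairs of the proliferating stages have multinomial
#' conditional modes (births / exposure, deaths / exposure), with the
#' decay-weighted exposure used for the growth-limited stages.  Modes are
#' projected into the open prior box; a parameter whose exposure is zero is
#' skipped (its current value is kept) and reported in the `skipped`
#' attribute.
#'
#' @param latents a `colon_latents` object from [augment_latents()].
#' @param prior a [default_prior()] box.
#' @param params current [colon_params()].
#' @return Updated `colon_params` (with attribute `skipped`).
#' @export
conditional_update_theta1 <- function(latents, prior, params) {
  s <- latents$selected_stats
  v <- param_vector(params)
  skipped <- character(0)
  upd <- function(name, events, exposure) {
    if (exposure <= 0) {
      skipped <<- c(skipped, name)
      return()
    }
    v[name] <<- clamp_open(events / exposure, prior[[name]])
  }
  upd("lambda_I", s$M0_I, s$steps * s$cohort_size)
  upd("lambda_J", s$M0_J, s$steps * s$cohort_size)
  upd("alpha1", s$M_I[1], s$expo_I[1])
  upd("alpha2", s$M_I[2], s$expo_I[2])
  upd("beta1", s$M_J[1], s$expo_J[1])
  upd("beta2", s$M_J[2], s$expo_J[2])
  upd("beta3", s$M_J[3], s$expo_J[3])
  # multinomial modes for the proliferating stages; net proliferation is
  # re-derived and kept inside its own box
  bd <- function(bname, gname, Bcount, Dcount, expo_b, expo_d) {
    if (expo_b <= 0 || expo_d <= 0) {
      skipped <<- c(skipped, bname)
      return()
    }
    b <- clamp_open(Bcount / expo_b, prior[[bname]])
    d <- Dcount / expo_d
    g <- clamp_open(b - d, prior[[gname]])
    v[bname] <<- max(b, g)
    v[gname] <<- g
  }
  bd("b_I2", "gamma_I2", s$B["I2"], s$D["I2"], s$expo_decay["I2"], s$expo_I[2])
  bd("b_I3", "gamma_I3", s$B["I3"], s$D["I3"], s$expo_I[3], s$expo_I[3])
  bd("b_J3", "gamma_J3", s$B["J3"], s$D["J3"], s$expo_decay["J3"], s$expo_J[3])
  bd("b_J4", "gamma_J4", s$B["J4"], s$D["J4"], s$expo_J[4], s$expo_J[4])
  out <- set_param_vector(params, v)
  attr(out, "skipped") <- skipped
  out
}

# negative log conditional posterior of the observation layer (Poisson
# incidence likelihood at the expected-number onset probabilities; the flat
# prior contributes nothing inside the box)
incidence_nll <- function(params, table, engine = "grid") {
  tau <- tryCatch(expected_cases(params, table, engine = engine),
                  error = function(e) NULL)
  if (is.null(tau) || any(!is.finite(tau))) return(1e10)
  ll <- suppressWarnings(poisson_loglik(table, pmax(tau, 1e-300)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# bounded maximisation of the conditional posterior over a named block of
# free parameters (log scale, warm-started, box = prior support)
optimize_block <- function(params, table, prior, free, maxit = 10,
                           engine = "grid") {
  lo <- log(vapply(prior[free], `[`, numeric(1), 1))
  hi <- log(vapply(prior[free], `[`, numeric(1), 2))
  v0 <- param_vector(params)[free]
  init <- pmin(pmax(log(v0), lo + 1e-8), hi - 1e-8)
  obj <- function(lth) {
    v <- stats::setNames(exp(lth), free)
    q <- tryCatch(set_param_vector(params, v), error = function(e) NULL)
    if (is.null(q)) return(1e10)
    incidence_nll(q, table, engine = engine)
  }
  fit <- stats::optim(init, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = maxit, factr = 1e7))
  v <- stats::setNames(exp(fit$par), free)
  list(params = set_param_vector(params, v), value = fit$value,
       convergence = fit$convergence, counts = fit$counts)
}

#' Conditional-mode update of the terminal mutation rates
#'
#' The terminal mutation rates (`alpha_3`, `beta_4`) enter the observation
#' layer directly (they scale the tumour-onset intensities), so their
#' conditional posterior given everything else is the Poisson incidence
#' likelihood restricted to the prior box.  It is maximised by bounded 2-D
#' quasi-Newton search on the log scale.
#'
#' @param params current [colon_params()].
#' @param table an [incidence_table()].
#' @param prior a [default_prior()] box.
#' @param maxit optimizer iteration cap.
#' @param engine see [cumulative_intensity()].
#' @return List with updated `params`, the attained negative log posterior
#'   `value` and the optimizer `convergence` code.
#' @export
conditional_update_theta2 <- function(params, table, prior = default_prior(),
                                      maxit = 25, engine = "grid") {
  optimize_block(params, table, prior, c("alpha3", "beta4"),
                 maxit = maxit, engine = engine)
}

#' Conditional-mode update of the proliferation / growth-limiting block
#'
#' The net proliferation rates, the polyp-stage birth rates (which set the
#' amplitude of the growth-limited decay) and the decay constants shape the
#' expected last-stage cell numbers and hence the onset probabilities; their
#' conditional posterior is maximised numerically inside the prior box.
#'
#' @inheritParams conditional_update_theta2
#' @return As [conditional_update_theta2()].
#' @export
conditional_update_growth <- function(params, table, prior = default_prior(),
                                      maxit = 10, engine = "grid") {
  free <- c("b_I2", "gamma_I2", "delta1", "gamma_I3",
            "b_J3", "gamma_J3", "delta2", "gamma_J4")
  optimize_block(params, table, prior, free, maxit = maxit, engine = engine)
}

#' Fitting configuration
#'
#' @param n_burnin recycling cycles discarded before draws are collected.
#' @param n_draws post-burn-in cycles retained as posterior draws.
#' @param n_chains independent chains; the first starts from the
#'   deterministic initialisation, the others from overdispersed starting
#'   points drawn log-uniformly over the prior box of the
#'   observation-identified block.
#' @param chain_nll_window chains whose final negative log posterior lies
#'   more than this many units above the best chain are treated as trapped
#'   in an inferior mode and excluded from the pooled draws (all chains are
#'   kept in the diagnostics).
#' @param K candidate latent paths per augmentation step.
#' @param optim_maxit per-cycle iteration cap of the numeric block updates.
#' @param tol relative drift between consecutive windowed means of the mode
#'   sequence below which a chain counts as converged.
#' @param conv_window cycles per convergence window.
#' @param engine expected-number engine on the fitting hot path.
#' @param p_free free-parameter count used for AIC/BIC (reported alongside).
#' @param dt_months,N_stem,detect_lag model conventions, see
#'   [colon_params()].
#' @return List of class `colon_fit_config`.
#' @export
fit_config <- function(n_burnin = 15, n_draws = 20, n_chains = 4, K = 10,
                       cohort_size = 2000, optim_maxit = 30, tol = 1e-2,
                       conv_window = 5, chain_nll_window = 20,
                       engine = "grid", p_free = 15,
                       dt_months = 3, N_stem = 1e8, detect_lag = 1) {
  structure(list(n_burnin = n_burnin, n_draws = n_draws, n_chains = n_chains,
                 K = K, cohort_size = cohort_size,
                 optim_maxit = optim_maxit, tol = tol,
                 conv_window = conv_window,
                 chain_nll_window = chain_nll_window,
                 engine = engine, p_free = p_free,
                 dt_months = dt_months, N_stem = N_stem,
                 detect_lag = detect_lag),
            class = "colon_fit_config")
}

#' Fit the two-pathway model to an incidence table
#'
#' Runs the multi-level Gibbs procedure (augmentation, conditional-mode
#' updates, recycling) for `n_chains` chains, collects the post-burn-in
#' parameter modes as posterior draws, and reports their sample means as
#' the estimates, together with the deviance, AIC/BIC (with the `p` and `n`
#' conventions stated explicitly) and the predicted case counts.
#'
#' Initialisation is deterministic: the parameters identified by the
#' observation layer (the terminal mutation rates and the proliferation /
#' growth-limiting block) start at the geometric midpoint of their prior
#' intervals, a neutral choice; the initiation intensities and non-terminal
#' mutation rates -- whose conditional updates follow the latent paths and
#' therefore stay near their starting scale -- start at the published point
#' estimates, i.e. at the prior knowledge the generalized-Bayesian
#' procedure is designed to incorporate.
#'
#' @param table an [incidence_table()].
#' @param prior a [default_prior()] box.
#' @param config a [fit_config()].
#' @param seed integer seed; chains use seeds derived from it.
#' @return A `colon_fit` object.
#' @export
gibbs_fit <- function(table, prior = default_prior(), config = fit_config(),
                      seed = 1) {
  table <- validate_incidence_table(as.data.frame(table))
  template <- default_params(dt_months = config$dt_months,
                             N_stem = config$N_stem,
                             detect_lag = config$detect_lag)
  v0 <- prior_midpoint(prior)
  latent_only <- c("lambda_I", "lambda_J", "alpha1", "alpha2",
                   "beta1", "beta2", "beta3")
  v0[latent_only] <- vapply(latent_only, function(nm)
    clamp_open(param_vector(template)[[nm]], prior[[nm]]), numeric(1))
  v0["b_I2"] <- max(v0["b_I2"], v0["gamma_I2"])
  v0["b_J3"] <- max(v0["b_J3"], v0["gamma_J3"])
  init <- set_param_vector(template, v0)
  n_cycles <- config$n_burnin + config$n_draws
  y_block <- c("b_I2", "gamma_I2", "delta1", "gamma_I3",
               "b_J3", "gamma_J3", "delta2", "gamma_J4", "alpha3", "beta4")
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed((seed + 1009L * (ch - 1L)) %% .Machine$integer.max)
    th <- init
    if (ch > 1L) {
      # overdispersed start: observation-identified block drawn
      # log-uniformly over its prior intervals
      v <- param_vector(th)
      v[y_block] <- vapply(y_block, function(nm) {
        b <- prior[[nm]]
        exp(stats::runif(1, log(b[1]), log(b[2])))
      }, numeric(1))
      v["b_I2"] <- max(v["b_I2"], v["gamma_I2"])
      v["b_J3"] <- max(v["b_J3"], v["gamma_J3"])
      th <- set_param_vector(th, v)
    }
    hist <- matrix(NA_real_, n_cycles, length(param_vector(th)),
                   dimnames = list(NULL, names(param_vector(th))))
    ess <- numeric(n_cycles)
    opt_codes <- integer(n_cycles)
    for (cy in seq_len(n_cycles)) {
      lat <- augment_latents(th, table, config$K,
                             cohort_size = config$cohort_size)
      ess[cy] <- lat$ess
      th <- conditional_update_theta1(lat, prior, th)
      # joint conditional-mode maximisation over the observation-coupled
      # block (proliferation/growth-limiting and terminal mutation rates)
      up <- optimize_block(th, table, prior, y_block,
                           maxit = config$optim_maxit,
                           engine = config$engine)
      th <- up$params
      opt_codes[cy] <- up$convergence
      hist[cy, ] <- param_vector(th)
    }
    # mode-sequence convergence: the augmentation step injects stationary
    # noise into every cycle, so stability is assessed on windowed means --
    # the mean over the last conv_window cycles must agree with the mean
    # over the preceding window to within tol, componentwise
    W <- config$conv_window
    converged <- if (n_cycles >= 2 * W) {
      m_prev <- colMeans(hist[(n_cycles - 2 * W + 1):(n_cycles - W), ,
                              drop = FALSE])
      m_last <- colMeans(hist[(n_cycles - W + 1):n_cycles, , drop = FALSE])
      max(abs(m_last / m_prev - 1)) < config$tol
    } else FALSE
    chains[[ch]] <- list(history = hist, ess = ess, mode = hist[n_cycles, ],
                         opt_codes = opt_codes, converged = converged,
                         nll = incidence_nll(th, table,
                                             engine = config$engine),
                         draws = hist[(config$n_burnin + 1L):n_cycles, ,
                                      drop = FALSE])
  }
  chain_nll <- vapply(chains, `[[`, numeric(1), "nll")
  keep <- chain_nll <= min(chain_nll) + config$chain_nll_window
  # candidate estimates: the pooled draw mean and each retained chain's own
  # draw mean.  Chains can settle in different posterior ridges, and the
  # mean of draws from two ridges need not lie near either; the reported
  # estimate is the candidate with the best posterior (mode-seeking, in
  # line with the procedure's posterior-mode updates).
  pools <- c(list(which(keep)), as.list(which(keep)))
  cand_nll <- vapply(pools, function(idx) {
    m <- colMeans(do.call(rbind, lapply(chains[idx], `[[`, "draws")))
    incidence_nll(set_param_vector(template, m), table,
                  engine = config$engine)
  }, numeric(1))
  keep <- pools[[which.min(cand_nll)]]
  draws <- do.call(rbind, lapply(chains[keep], `[[`, "draws"))
  est <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  params_hat <- set_param_vector(template, est)
  tau_hat <- expected_cases(params_hat, table, engine = config$engine)
  dev <- poisson_deviance(table, tau_hat)
  ic <- information_criteria(dev, config$p_free, nrow(table))
  structure(list(
    estimates = est, se = sqrt(vars), draws = draws,
    params_hat = params_hat, predicted = tau_hat,
    deviance = dev, AIC = ic$AIC, BIC = ic$BIC,
    p = ic$p, n_points = ic$n_points,
    converged = all(vapply(chains[keep], `[[`, logical(1), "converged")),
    chains = chains, chains_pooled = keep,
    table = table, prior = prior, config = config,
    seed = seed
  ), class = "colon_fit")
}

#' @export
print.colon_fit <- function(x, ...) {
  cat("Two-pathway model fit (generalized Bayesian, multi-level Gibbs)\n")
  cat(sprintf("  chains: %d, draws: %d, converged: %s\n",
              x$config$n_chains, nrow(x$draws), x$converged))
  cat(sprintf("  deviance = %.2f,  AIC = %.2f,  BIC = %.2f  (p = %d, n = %d)\n",
              x$deviance, x$AIC, x$BIC, x$p, x$n_points))
  cat("  estimates (posterior means):\n")
  print(signif(x$estimates, 3))
  invisible(x)
}

#' Predicted case counts with posterior spread
#'
#' Evaluates the expected case counts at the posterior-mean parameters and,
#' across the retained posterior draws, the pointwise predictive quantiles.
#'
#' @param fit a `colon_fit` from [gibbs_fit()].
#' @param table incidence table to predict for (defaults to the fitted one).
#' @param level central interval level for the draw-wise spread.
#' @param force predict even from a non-converged fit.
#' @return The table with columns `predicted`, `lower`, `upper` appended.
#' @export
predict_incidence <- function(fit, table = fit$table, level = 0.95,
                              force = FALSE) {
  if (!fit$converged && !force)
    stop("fit did not converge; rerun with more cycles or use force = TRUE",
         call. = FALSE)
  table <- validate_incidence_table(as.data.frame(table))
  engine <- fit$config$engine
  tau_hat <- expected_cases(fit$params_hat, table, engine = engine)
  tau_draws <- apply(fit$draws, 1, function(v) {
    expected_cases(set_param_vector(fit$params_hat, v), table,
                   engine = engine)
  })
  tau_draws <- matrix(tau_draws, nrow = nrow(table))
  alpha <- (1 - level) / 2
  qs <- apply(tau_draws, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- as.data.frame(table)
  out$predicted <- tau_hat
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  class(out) <- c("incidence_prediction", "data.frame")
  out
}
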