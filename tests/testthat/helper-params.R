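# shared helpers: parameter draws from the prior box and small fixtures

# log-uniform draw from the prior box; time-homogeneous (delta = 0) unless
# requested, with birth rates lifted so death rates stay nonnegative
draw_prior_params <- function(with_decay = FALSE) {
  pr <- default_prior()
  lu <- function(nm) exp(stats::runif(1, log(pr[[nm]][1]), log(pr[[nm]][2])))
  g <- c(gamma_I2 = lu("gamma_I2"), gamma_I3 = lu("gamma_I3"),
         gamma_J3 = lu("gamma_J3"), gamma_J4 = lu("gamma_J4"))
  v <- c(lambda_I = lu("lambda_I"), lambda_J = lu("lambda_J"),
         alpha1 = lu("alpha1"), alpha2 = lu("alpha2"), alpha3 = lu("alpha3"),
         beta1 = lu("beta1"), beta2 = lu("beta2"), beta3 = lu("beta3"),
         beta4 = lu("beta4"),
         b_I2 = max(lu("b_I2"), g[["gamma_I2"]]),
         b_I3 = max(lu("b_I3"), g[["gamma_I3"]]),
         b_J3 = max(lu("b_J3"), g[["gamma_J3"]]),
         b_J4 = max(lu("b_J4"), g[["gamma_J4"]]),
         g,
         delta1 = if (with_decay) lu("delta1") else 0,
         delta2 = if (with_decay) lu("delta2") else 0)
  set_param_vector(default_params(), v)
}

# a small parameter set with quiet dynamics, cheap to simulate exactly
small_params <- function(...) {
  p <- colon_params(
    lambda_I = 5, lambda_J = 3,
    alpha = c(2e-3, 5e-3, 1e-4),
    beta = c(1e-3, 2e-3, 4e-3, 1e-4),
    b_I = c(0, 8e-3, 2e-2), d_I = c(0, 4e-3, 5e-3),
    b_J = c(0, 0, 1e-2, 2.5e-2), d_J = c(0, 0, 7e-3, 6e-3),
    delta1 = 0, delta2 = 0
  )
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  if (length(mods)) p <- colonmsce:::validate_params(p)
  p
}

# zero-rate parameter set (nothing ever happens)
null_params <- function() {
  colon_params(lambda_I = 0, lambda_J = 0,
               alpha = rep(0, 3), beta = rep(0, 4),
               b_I = rep(0, 3), d_I = rep(0, 3),
               b_J = rep(0, 4), d_J = rep(0, 4))
}

# compact risk schedule for fast incidence-model checks
small_schedule <- function() {
  data.frame(age_lo = c(0, 20, 40, 60), age_hi = c(20, 40, 60, 80),
             n = c(1e6, 1e6, 8e5, 5e5))
}
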