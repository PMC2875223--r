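# The partially informative prior: constant density inside a box of
# biologically motivated open intervals, zero outside.
#
# The initiation intensities and the proliferation / growth-limiting bounds
# follow the published constraints (1 < lambda < 1000; polyp-stage net
# proliferation in (1e-4, 2e-2) with decay constant in (1e-5, 5e-3);
# last-stage net proliferation in (1e-2, 0.5); birth rates below 0.5).  The
# per-stage mutation-rate bounds printed with the model are mutually
# inconsistent with its own published estimates (the instability-boosted
# transitions sit two orders of magnitude above the printed ceiling), so the
# default box uses one generous mutation-rate interval (1e-8, 1e-2) that
# contains every published estimate; the MSI proliferation bounds, absent
# from the source, mirror the CIN ones stage-for-stage.

#' Default prior box for the model parameters
#'
#' @return A named list of `c(lower, upper)` open intervals, one per free
#'   parameter, of class `colon_prior`.
#' @seealso [log_prior()], [param_vector()]
#' @export
default_prior <- function() {
  mut <- c(1e-8, 1e-2)
  structure(list(
    lambda_I = c(1, 1000), lambda_J = c(1, 1000),
    alpha1 = mut, alpha2 = mut, alpha3 = mut,
    beta1 = mut, beta2 = mut, beta3 = mut, beta4 = mut,
    b_I2 = c(1e-4, 0.5), b_I3 = c(1e-4, 0.5),
    b_J3 = c(1e-4, 0.5), b_J4 = c(1e-4, 0.5),
    gamma_I2 = c(1e-4, 2e-2), gamma_I3 = c(1e-2, 0.5),
    gamma_J3 = c(1e-4, 2e-2), gamma_J4 = c(1e-2, 0.5),
    delta1 = c(1e-5, 5e-3), delta2 = c(1e-5, 5e-3)
  ), class = "colon_prior")
}

#' @export
print.colon_prior <- function(x, ...) {
  cat("Partially informative prior (flat inside open box):\n")
  for (nm in names(x))
    cat(sprintf("  %-9s (%g, %g)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Free-parameter vector of a parameter set
#'
#' Extracts (or writes back) the free parameters the fitting procedure
#' works with: initiation intensities, stage mutation rates, the birth rates
#' of the proliferating stages, the net proliferation rates (derived
#' `b - d`) and the growth-limiting decay constants.
#'
#' @param params a [colon_params()] object.
#' @return Named numeric vector.
#' @export
param_vector <- function(params) {
  g <- proliferation_rates(params)
  c(lambda_I = params$lambda_I, lambda_J = params$lambda_J,
    alpha1 = params$alpha[1], alpha2 = params$alpha[2],
    alpha3 = params$alpha[3],
    beta1 = params$beta[1], beta2 = params$beta[2], beta3 = params$beta[3],
    beta4 = params$beta[4],
    b_I2 = params$b_I[2], b_I3 = params$b_I[3],
    b_J3 = params$b_J[3], b_J4 = params$b_J[4],
    gamma_I2 = g$gamma_I[2], gamma_I3 = g$gamma_I[3],
    gamma_J3 = g$gamma_J[3], gamma_J4 = g$gamma_J[4],
    delta1 = params$delta1, delta2 = params$delta2)
}

#' @rdname param_vector
#' @param v named vector as returned by `param_vector()` (a subset of names
#'   is allowed; omitted parameters keep their current values).
#' @details When a net proliferation rate exceeds its birth rate the birth
#'   rate is lifted to keep the death rate nonnegative.
#' @export
set_param_vector <- function(params, v) {
  q <- params
  pick <- function(nm, cur) if (nm %in% names(v)) unname(v[[nm]]) else cur
  q$lambda_I <- pick("lambda_I", q$lambda_I)
  q$lambda_J <- pick("lambda_J", q$lambda_J)
  q$alpha <- c(pick("alpha1", q$alpha[1]), pick("alpha2", q$alpha[2]),
               pick("alpha3", q$alpha[3]))
  q$beta <- c(pick("beta1", q$beta[1]), pick("beta2", q$beta[2]),
              pick("beta3", q$beta[3]), pick("beta4", q$beta[4]))
  g <- proliferation_rates(params)
  gI2 <- pick("gamma_I2", g$gamma_I[2]); gI3 <- pick("gamma_I3", g$gamma_I[3])
  gJ3 <- pick("gamma_J3", g$gamma_J[3]); gJ4 <- pick("gamma_J4", g$gamma_J[4])
  bI2 <- max(pick("b_I2", q$b_I[2]), gI2)
  bI3 <- max(pick("b_I3", q$b_I[3]), gI3)
  bJ3 <- max(pick("b_J3", q$b_J[3]), gJ3)
  bJ4 <- max(pick("b_J4", q$b_J[4]), gJ4)
  q$b_I <- c(0, bI2, bI3); q$d_I <- c(0, bI2 - gI2, bI3 - gI3)
  q$b_J <- c(0, 0, bJ3, bJ4); q$d_J <- c(0, 0, bJ3 - gJ3, bJ4 - gJ4)
  q$delta1 <- pick("delta1", q$delta1)
  q$delta2 <- pick("delta2", q$delta2)
  validate_params(q)
}

#' Log prior density (up to a constant)
#'
#' Zero (the constant reference level) when every free parameter lies
#' strictly inside its prior interval, `-Inf` otherwise.  Boundary values
#' count as outside (the intervals are open).
#'
#' @param params a [colon_params()] object.
#' @param prior a prior box from [default_prior()].
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(params, prior = default_prior()) {
  v <- param_vector(params)
  for (nm in names(prior)) {
    b <- prior[[nm]]
    if (!(v[[nm]] > b[1] && v[[nm]] < b[2])) return(-Inf)
  }
  0
}

# clamp a value strictly inside an open interval
clamp_open <- function(x, bounds, frac = 1e-9) {
  eps <- frac * (bounds[2] - bounds[1])
  pmin(pmax(x, bounds[1] + eps), bounds[2] - eps)
}

# geometric midpoint initialisation: rates are scale parameters, so the
# neutral deterministic start is the geometric centre of each interval
prior_midpoint <- function(prior) {
  v <- vapply(prior, function(b) sqrt(b[1] * b[2]), numeric(1))
  # keep death rates nonnegative: lift birth rates to their net
  # proliferation rates where needed
  v["b_I2"] <- max(v["b_I2"], v["gamma_I2"])
  v["b_I3"] <- max(v["b_I3"], v["gamma_I3"])
  v["b_J3"] <- max(v["b_J3"], v["gamma_J3"])
  v["b_J4"] <- max(v["b_J4"], v["gamma_J4"])
  v
}
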