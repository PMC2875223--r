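#' Parameter set for the two-pathway colon carcinogenesis model
#'
#' Builds and validates the full rate set of the two-pathway multistage
#' clonal-expansion model of colon cancer.  Pathway 1 is the chromosomal
#' instability (CIN) route with `k1 = 4` rate-limiting stages (intermediate
#' cell compartments `I1..I3`); pathway 2 is the microsatellite instability
#' (MSI) route with `k2 = 5` stages (compartments `J1..J4`).  All rates are
#' per cell per model time unit; one time unit corresponds to `dt_months`
#' calendar months (3 months by default).
#'
#' Initiation is parameterized directly by the expected number of
#' normal-to-first-stage transitions per time unit, `lambda_I = N * alpha0`
#' and `lambda_J = N * beta0`, where `N` is the (constant) normal stem-cell
#' count; `N_stem` is retained so that per-cell initiation rates can be
#' recovered at the I/O edge.
#'
#' Proliferation is restricted biologically: the first CIN stage and the
#' first two MSI stages do not proliferate (their birth and death rates are
#' zero).  The polyp-forming stages (`I2` and `J3`) have growth-limited
#' proliferation: their birth rate decays as `b * exp(-delta * t)` with the
#' growth-limiting parameter `delta` (adenomas only grow to a maximum size).
#' The net proliferation rate `gamma = b - d` is always derived, never stored.
#'
#' @param lambda_I,lambda_J expected initiations per time unit for the CIN
#'   and MSI pathways (`N -> I1`, `N -> J1`).
#' @param alpha numeric length 3; per-cell mutation rates `I_l -> I_(l+1)`,
#'   `l = 1..3`.  `alpha[3]` is the rate at which last-stage CIN cells found
#'   detectable tumours.
#' @param beta numeric length 4; per-cell mutation rates `J_r -> J_(r+1)`,
#'   `r = 1..4`.
#' @param b_I,d_I numeric length 3; per-cell birth and death rates of
#'   `I1..I3`.  Stage 1 must be zero.
#' @param b_J,d_J numeric length 4; per-cell birth and death rates of
#'   `J1..J4`.  Stages 1 and 2 must be zero.
#' @param delta1,delta2 growth-limiting decay parameters for the birth rates
#'   of `I2` and `J3` (per time unit).
#' @param dt_months calendar months per model time unit.
#' @param N_stem normal stem-cell count used to convert per-cell initiation
#'   rates to `lambda` (and back).
#' @param detect_lag detection lag in time units: a tumour founded at time
#'   `s` is detectable at `t` iff `t - s >= detect_lag`.
#'
#' @return An object of class `colon_params`.
#' @seealso [default_params()] for the published point estimates,
#'   [stage_rates()], [expected_numbers()].
#' @export
colon_params <- function(lambda_I, lambda_J,
                         alpha, beta,
                         b_I, d_I, b_J, d_J,
                         delta1 = 0, delta2 = 0,
                         dt_months = 3, N_stem = 1e8, detect_lag = 1) {
  p <- structure(
    list(
      k1 = 4L, k2 = 5L,
      lambda_I = as.numeric(lambda_I), lambda_J = as.numeric(lambda_J),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      b_I = as.numeric(b_I), d_I = as.numeric(d_I),
      b_J = as.numeric(b_J), d_J = as.numeric(d_J),
      delta1 = as.numeric(delta1), delta2 = as.numeric(delta2),
      dt_months = as.numeric(dt_months),
      N_stem = as.numeric(N_stem),
      detect_lag = as.numeric(detect_lag)
    ),
    class = "colon_params"
  )
  validate_params(p)
}

validate_params <- function(p) {
  stopifnot(length(p$alpha) == p$k1 - 1L, length(p$beta) == p$k2 - 1L,
            length(p$b_I) == p$k1 - 1L, length(p$d_I) == p$k1 - 1L,
            length(p$b_J) == p$k2 - 1L, length(p$d_J) == p$k2 - 1L)
  rates <- c(p$lambda_I, p$lambda_J, p$alpha, p$beta,
             p$b_I, p$d_I, p$b_J, p$d_J, p$delta1, p$delta2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and nonnegative", call. = FALSE)
  if (any(c(p$alpha, p$beta, p$b_I, p$d_I, p$b_J, p$d_J) >= 1))
    stop("per-cell per-time-unit rates must be < 1", call. = FALSE)
  # multinomial validity of the birth/death draw: (b + d) * dt <= 1 per unit
  # (stage mutations are independent Poisson draws and do not deplete the
  # stage, so they do not enter the multinomial constraint)
  tot_I <- p$b_I + p$d_I
  tot_J <- p$b_J + p$d_J
  if (any(tot_I > 1))
    stop("CIN stage I", which.max(tot_I),
         ": (b + d) * dt exceeds 1; shrink dt_months", call. = FALSE)
  if (any(tot_J > 1))
    stop("MSI stage J", which.max(tot_J),
         ": (b + d) * dt exceeds 1; shrink dt_months", call. = FALSE)
  if (p$b_I[1] != 0 || p$d_I[1] != 0)
    stop("stage I1 must not proliferate", call. = FALSE)
  if (any(p$b_J[1:2] != 0) || any(p$d_J[1:2] != 0))
    stop("stages J1 and J2 must not proliferate", call. = FALSE)
  if (p$dt_months <= 0) stop("dt_months must be positive", call. = FALSE)
  if (p$detect_lag < 0) stop("detect_lag must be nonnegative", call. = FALSE)
  p
}

#' Published point estimates as a ready-to-use parameter set
#'
#' Returns the reference estimates for the two-pathway model fitted to the
#' SEER colon cancer incidence table: mutation rates, birth rates, net
#' proliferation rates (death rate = birth - proliferation) and
#' growth-limiting parameters for each pathway.  Initiation intensities are
#' the per-cell rates (1.4e-6 for CIN, 8.3e-7 for MSI) scaled by `N_stem`
#' normal stem cells.
#'
#' @param dt_months,N_stem,detect_lag time-unit, stem-cell and detection
#'   conventions, see [colon_params()].
#' @return A `colon_params` object.
#' @export
default_params <- function(dt_months = 3, N_stem = 1e8, detect_lag = 1) {
  alpha0 <- 1.4e-6
  beta0  <- 8.3e-7
  # CIN: stages I1..I3
  alpha   <- c(2.2e-4, 3.2e-3, 1.2e-6)
  b_I     <- c(0, 7.4e-3, 1.9e-2)
  gamma_I <- c(0, 3.6e-3, 1.6e-2)
  # MSI: stages J1..J4
  beta    <- c(3.5e-4, 1.4e-3, 9.3e-3, 7.7e-6)
  b_J     <- c(0, 0, 9.6e-3, 2.6e-2)
  gamma_J <- c(0, 0, 2.8e-3, 2.0e-2)
  colon_params(
    lambda_I = N_stem * alpha0, lambda_J = N_stem * beta0,
    alpha = alpha, beta = beta,
    b_I = b_I, d_I = b_I - gamma_I,
    b_J = b_J, d_J = b_J - gamma_J,
    delta1 = 8.3e-5, delta2 = 1.6e-3,
    dt_months = dt_months, N_stem = N_stem, detect_lag = detect_lag
  )
}

#' Net proliferation rates (derived, never stored)
#'
#' @param params a `colon_params` object.
#' @return List with components `gamma_I` (length 3) and `gamma_J` (length 4),
#'   the time-zero net proliferation rates `b - d` per stage.
#' @export
proliferation_rates <- function(params) {
  list(gamma_I = params$b_I - params$d_I,
       gamma_J = params$b_J - params$d_J)
}

#' Per-stage rates at a given time
#'
#' Mutation rates are time-constant.  The birth rates of the polyp-forming
#' stages (`I2`, `J3`) decay exponentially with the growth-limiting
#' parameters: `b(t) = b * exp(-delta * t)`; all other birth and death rates
#' are constant.
#'
#' @param params a `colon_params` object.
#' @param t time in model units (scalar, `t >= 0`).
#' @return List with components `lambda_I`, `lambda_J`, `alpha`, `beta`,
#'   `b_I`, `d_I`, `b_J`, `d_J` evaluated at `t`.
#' @export
stage_rates <- function(params, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a nonnegative scalar time", call. = FALSE)
  b_I <- params$b_I
  b_J <- params$b_J
  b_I[2] <- b_I[2] * exp(-params$delta1 * t)
  b_J[3] <- b_J[3] * exp(-params$delta2 * t)
  list(lambda_I = params$lambda_I, lambda_J = params$lambda_J,
       alpha = params$alpha, beta = params$beta,
       b_I = b_I, d_I = params$d_I,
       b_J = b_J, d_J = params$d_J)
}

#' Convert between years of age and model time units
#'
#' @param years,units age values to convert.
#' @param params a `colon_params` object supplying `dt_months`.
#' @return Numeric vector of converted times.
#' @export
years_to_units <- function(years, params) years * 12 / params$dt_months

#' @rdname years_to_units
#' @export
units_to_years <- function(units, params) units * params$dt_months / 12

#' @export
print.colon_params <- function(x, ...) {
  g <- proliferation_rates(x)
  cat("Two-pathway colon carcinogenesis model parameters\n")
  cat(sprintf("  time unit: %g months; N_stem = %g; detection lag = %g unit(s)\n",
              x$dt_months, x$N_stem, x$detect_lag))
  cat(sprintf("  CIN (k1 = %d): lambda_I = %g\n", x$k1, x$lambda_I))
  cat(sprintf("    alpha  = %s\n", paste(signif(x$alpha, 3), collapse = ", ")))
  cat(sprintf("    b_I    = %s\n", paste(signif(x$b_I, 3), collapse = ", ")))
  cat(sprintf("    d_I    = %s\n", paste(signif(x$d_I, 3), collapse = ", ")))
  cat(sprintf("    gamma_I= %s; delta1 = %g\n",
              paste(signif(g$gamma_I, 3), collapse = ", "), x$delta1))
  cat(sprintf("  MSI (k2 = %d): lambda_J = %g\n", x$k2, x$lambda_J))
  cat(sprintf("    beta   = %s\n", paste(signif(x$beta, 3), collapse = ", ")))
  cat(sprintf("    b_J    = %s\n", paste(signif(x$b_J, 3), collapse = ", ")))
  cat(sprintf("    d_J    = %s\n", paste(signif(x$d_J, 3), collapse = ", ")))
  cat(sprintf("    gamma_J= %s; delta2 = %g\n",
              paste(signif(g$gamma_J, 3), collapse = ", "), x$delta2))
  invisible(x)
}

#' Read or write a parameter set as a flat YAML file
#'
#' All rates are stored in per-time-unit units with `dt_months` recorded
#' alongside, so a file is self-describing.
#'
#' @param params a `colon_params` object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `colon_params` object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$k1 <- NULL; x$k2 <- NULL
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("lambda_I", "lambda_J", "alpha", "beta",
            "b_I", "d_I", "b_J", "d_J")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  colon_params(
    lambda_I = x$lambda_I, lambda_J = x$lambda_J,
    alpha = unlist(x$alpha), beta = unlist(x$beta),
    b_I = unlist(x$b_I), d_I = unlist(x$d_I),
    b_J = unlist(x$b_J), d_J = unlist(x$d_J),
    delta1 = x$delta1 %||% 0, delta2 = x$delta2 %||% 0,
    dt_months = x$dt_months %||% 3,
    N_stem = x$N_stem %||% 1e8,
    detect_lag = x$detect_lag %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
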