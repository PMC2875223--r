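# Expected numbers of initiated cells in the two pathways.
#
# Each pathway is a linear cascade driven by constant immigration lambda
# (initiation from normal stem cells), asymmetric mutation inflow from the
# previous stage and net proliferation gamma_l(t) = b_l(t) - d_l:
#
#   d u_1 / dt = lambda          + gamma_1(t) u_1
#   d u_l / dt = a_{l-1} u_{l-1} + gamma_l(t) u_l,   l >= 2
#
# with u_l(0) = 0.  Mutation is asymmetric (the mother cell survives), so no
# loss term appears.  Three solvers are provided: an exact closed form for
# time-homogeneous rates, a stiff ODE integrator (the numeric oracle, also
# covering the growth-limited time-varying birth rates), and a fast
# exponential-integrator cascade on the unit grid used in fitting.

# ---- exponential-polynomial closed form -------------------------------------
#
# Solutions are exact linear combinations of terms  coef * t^pow * exp(rate*t).
# Convolving such a term with exp(g (t - s)) stays in the family, including
# the degenerate cases rate == g (the power increments), so repeated or zero
# net proliferation rates need no separate limiting formulas.

ep_terms <- function(coef, pow, rate) {
  cbind(coef = coef, pow = pow, rate = rate)
}

ep_collapse <- function(terms) {
  key <- paste(terms[, "pow"], signif(terms[, "rate"], 15))
  coef <- tapply(terms[, "coef"], key, sum)
  keep <- match(names(coef), key)
  out <- ep_terms(as.numeric(coef), terms[keep, "pow"], terms[keep, "rate"])
  out <- out[abs(out[, "coef"]) > 0, , drop = FALSE]
  if (nrow(out) == 0L) out <- ep_terms(0, 0, 0)   # the zero function
  out
}

# u(t) = int_0^t exp(g (t - s)) f(s) ds for f given as ep terms
ep_conv <- function(terms, g, tol = 1e-9) {
  out <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    c0 <- terms[i, "coef"]; p <- terms[i, "pow"]; a <- terms[i, "rate"]
    if (abs(a - g) <= tol * max(1, abs(a), abs(g))) {
      out[[i]] <- ep_terms(c0 / (p + 1), p + 1, g)
    } else {
      mu <- a - g
      k <- 0:p
      coef_a <- c0 * (-1)^k * exp(lgamma(p + 1) - lgamma(p - k + 1)) / mu^(k + 1)
      coef_g <- c0 * (-1)^(p + 1) * gamma(p + 1) / mu^(p + 1)
      out[[i]] <- rbind(ep_terms(coef_a, p - k, a), ep_terms(coef_g, 0, g))
    }
  }
  ep_collapse(do.call(rbind, out))
}

ep_eval <- function(terms, t) {
  vapply(t, function(tt) {
    sum(terms[, "coef"] * tt^terms[, "pow"] * exp(terms[, "rate"] * tt))
  }, numeric(1))
}

# closed-form term representation for every compartment of both pathways;
# requires time-homogeneous rates (delta1 = delta2 = 0)
closed_form_terms <- function(params) {
  g <- proliferation_rates(params)
  cascade <- function(lambda, mut, gam) {
    n <- length(gam)
    terms <- vector("list", n)
    terms[[1]] <- ep_conv(ep_terms(lambda, 0, 0), gam[1])
    for (l in seq_len(n)[-1]) {
      inflow <- terms[[l - 1]]
      inflow[, "coef"] <- inflow[, "coef"] * mut[l - 1]
      terms[[l]] <- ep_conv(inflow, gam[l])
    }
    terms
  }
  list(I = cascade(params$lambda_I, params$alpha, g$gamma_I),
       J = cascade(params$lambda_J, params$beta, g$gamma_J))
}

#' Expected numbers of initiated cells
#'
#' Closed-form expected counts `E[I_l(t)]`, `E[J_r(t)]` for time-homogeneous
#' rates, obtained by nested convolution of the immigration-mutation cascade
#' (exact exponential-polynomial solution, valid also when net proliferation
#' rates coincide or vanish).  When a growth-limiting decay is active
#' (`delta1 > 0` or `delta2 > 0`) the rates are time-varying and the call
#' falls through to the numeric integrator [expected_numbers_ode()].
#'
#' @param params a [colon_params()] object.
#' @param t time(s) in model units, nonnegative.
#' @return An `expected_state` list with elements `t`, `uI` (matrix, one
#'   column per CIN stage) and `uJ` (matrix, one column per MSI stage).
#' @export
expected_numbers <- function(params, t) {
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (params$delta1 > 0 || params$delta2 > 0)
    return(expected_numbers_ode(params, t))
  tm <- closed_form_terms(params)
  uI <- vapply(tm$I, ep_eval, numeric(length(t)), t = t)
  uJ <- vapply(tm$J, ep_eval, numeric(length(t)), t = t)
  expected_state(t, matrix(uI, ncol = params$k1 - 1L),
                 matrix(uJ, ncol = params$k2 - 1L))
}

expected_state <- function(t, uI, uJ) {
  colnames(uI) <- paste0("I", seq_len(ncol(uI)))
  colnames(uJ) <- paste0("J", seq_len(ncol(uJ)))
  structure(list(t = t, uI = uI, uJ = uJ), class = "expected_state")
}

#' @export
print.expected_state <- function(x, ...) {
  cat("Expected initiated-cell numbers at", length(x$t), "time point(s)\n")
  print(utils::head(cbind(t = x$t, x$uI, x$uJ)))
  invisible(x)
}

# time derivative of all compartments (+ cumulative tumour intensities)
state_deriv <- function(t, u, params) {
  r <- stage_rates(params, t)
  gI <- r$b_I - r$d_I
  gJ <- r$b_J - r$d_J
  uI <- u[1:3]; uJ <- u[4:7]
  duI <- c(r$lambda_I, r$alpha[1] * uI[1], r$alpha[2] * uI[2]) + gI * uI
  duJ <- c(r$lambda_J, r$beta[1] * uJ[1], r$beta[2] * uJ[2],
           r$beta[3] * uJ[3]) + gJ * uJ
  dH <- c(r$alpha[3] * uI[3], r$beta[4] * uJ[4])
  list(c(duI, duJ, dH))
}

#' Expected numbers by numeric ODE integration
#'
#' Integrates the expected-number differential equations with a stiff solver
#' (`deSolve::lsoda`).  Serves as the independent oracle for the closed form
#' and handles the time-varying, growth-limited birth rates.
#'
#' @param params a [colon_params()] object.
#' @param t_grid increasing nonnegative times (model units).
#' @param rtol,atol solver tolerances.
#' @return An `expected_state` (see [expected_numbers()]) evaluated on
#'   `t_grid`.
#' @export
expected_numbers_ode <- function(params, t_grid, rtol = 1e-10, atol = 1e-40) {
  if (any(t_grid < 0)) stop("t_grid must be nonnegative", call. = FALSE)
  if (is.unsorted(t_grid, strictly = FALSE))
    stop("t_grid must be increasing", call. = FALSE)
  sol <- ode_solve(params, t_grid, rtol, atol)
  idx <- match(t_grid, sol[, "time"])
  expected_state(t_grid,
                 sol[idx, 2:4, drop = FALSE],
                 sol[idx, 5:8, drop = FALSE])
}

ode_solve <- function(params, times, rtol = 1e-10, atol = 1e-40) {
  times_all <- sort(unique(c(0, times)))
  y0 <- stats::setNames(numeric(9),
                        c(paste0("I", 1:3), paste0("J", 1:4), "H1", "H2"))
  sol <- withCallingHandlers(
    deSolve::lsoda(y = y0, times = times_all, func = state_deriv,
                   parms = params, rtol = rtol, atol = atol),
    warning = function(w) {
      stop("ODE integration failed: ", conditionMessage(w), call. = FALSE)
    }
  )
  if (anyNA(sol)) stop("ODE integration produced NA values", call. = FALSE)
  sol
}

# ---- fast unit-grid cascade -------------------------------------------------
#
# Exponential-integrator recursion on the grid t = 0, 1, ..., t_max (one model
# time unit per step): the homogeneous part is propagated exactly through the
# integrated net proliferation G(t) = int_0^t gamma(s) ds (available in closed
# form even under the exponential birth-rate decay), the mutation inflow by
# the trapezoid rule.  Used on the hot path of the fitting procedure.
expected_grid <- function(params, t_max) {
  t <- 0:t_max
  h <- 1
  g <- proliferation_rates(params)
  # integrated net proliferation per stage, as a function of grid time
  G_int <- function(b, d, delta) {
    if (delta > 0) b * (1 - exp(-delta * t)) / delta - d * t else (b - d) * t
  }
  stage_series <- function(inflow, b, d, delta) {
    # linear recurrence u[i+1] = E_i u[i] + c_i solved in closed form via
    # cumulative products: u[n+1] = P_n * sum_{i<=n} c_i / P_i.  |G| is
    # bounded by ~0.5 * t_max, so the products stay inside double range.
    G <- G_int(b, d, delta)
    E <- exp(diff(G))
    cc <- h / 2 * (E * inflow[-length(inflow)] + inflow[-1])
    P <- cumprod(E)
    c(0, P * cumsum(cc / P))
  }
  lin1 <- function(lambda, gam) {
    if (abs(gam) < 1e-14) lambda * t else lambda * (exp(gam * t) - 1) / gam
  }
  uI1 <- lin1(params$lambda_I, g$gamma_I[1])
  uI2 <- stage_series(params$alpha[1] * uI1, params$b_I[2], params$d_I[2],
                      params$delta1)
  uI3 <- stage_series(params$alpha[2] * uI2, params$b_I[3], params$d_I[3], 0)
  uJ1 <- lin1(params$lambda_J, g$gamma_J[1])
  uJ2 <- stage_series(params$beta[1] * uJ1, params$b_J[2], params$d_J[2], 0)
  uJ3 <- stage_series(params$beta[2] * uJ2, params$b_J[3], params$d_J[3],
                      params$delta2)
  uJ4 <- stage_series(params$beta[3] * uJ3, params$b_J[4], params$d_J[4], 0)
  list(t = t, uI = cbind(I1 = uI1, I2 = uI2, I3 = uI3),
       uJ = cbind(J1 = uJ1, J2 = uJ2, J3 = uJ3, J4 = uJ4))
}
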