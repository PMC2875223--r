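# Tumour-onset probabilities per age group and the Poisson observation model.
#
# Detectable tumours from pathway i arise as a nonhomogeneous Poisson process
# whose cumulative intensity omega_i(t) is the integral of (last-stage
# mutation rate) x (expected last-stage cell count) x (detection indicator).
# The probability of a first detectable tumour from pathway i in age group
# (t_{j-1}, t_j] is the first-event probability
#     Q_i(j) = exp(-omega_i(t_{j-1})) - exp(-omega_i(t_j)),
# and the two pathways combine by inclusion-exclusion,
#     Q_T(j) = Q_1(j) + Q_2(j) - Q_1(j) Q_2(j).
# With n_j people at risk the observed case count is approximately Poisson
# with mean tau_j = n_j Q_T(j), which yields the deviance used for AIC/BIC.

#' Age-grouped incidence table
#'
#' Container for age-specific cancer incidence: for each age group `j`,
#' the half-open age interval `[age_lo, age_hi)` in years, the number of
#' people at risk `n` and the observed case count `y`.
#'
#' @param age_lo,age_hi group bounds in years; groups must be non-overlapping
#'   and increasing.
#' @param n persons at risk per group.
#' @param y observed cases per group (`0 <= y <= n`).
#' @param predicted optional predicted case counts.
#' @return A `data.frame` of class `incidence_table`.
#' @export
incidence_table <- function(age_lo, age_hi, n, y, predicted = NULL) {
  tab <- data.frame(age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                    n = as.numeric(n), y = as.numeric(y))
  if (!is.null(predicted)) tab$predicted <- as.numeric(predicted)
  validate_incidence_table(tab)
}

validate_incidence_table <- function(tab) {
  need <- c("age_lo", "age_hi", "n", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("incidence table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$age_hi <= tab$age_lo))
    stop("age groups must have age_hi > age_lo", call. = FALSE)
  if (is.unsorted(tab$age_lo, strictly = TRUE) ||
      any(tab$age_lo[-1] < tab$age_hi[-nrow(tab)]))
    stop("age groups must be increasing and non-overlapping", call. = FALSE)
  if (any(tab$n < 0) || any(tab$y < 0) || any(tab$y > tab$n))
    stop("need 0 <= y <= n in every group", call. = FALSE)
  class(tab) <- c("incidence_table", "data.frame")
  tab
}

#' Cumulative tumour-onset intensities
#'
#' Computes the cumulative intensities `omega_1(t)` (CIN) and `omega_2(t)`
#' (MSI) of the detectable-tumour point processes, by quadrature of the
#' last-stage expected cell counts times the last-stage mutation rate, with
#' the detection-lag convention of the parameter set (a tumour founded at `s`
#' is detectable at `t` only if `t - s >= detect_lag`):
#' `omega_i(t) = integral_0^(t - lag) rate * u_last(s) ds`.
#'
#' @param params a [colon_params()] object.
#' @param t times in model units.
#' @param engine `"ode"` for the stiff-solver expected numbers (default),
#'   `"grid"` for the fast unit-grid cascade used in fitting.
#' @return Matrix with columns `omega1`, `omega2`, one row per element of `t`.
#' @export
cumulative_intensity <- function(params, t, engine = c("ode", "grid")) {
  engine <- match.arg(engine)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  ts <- pmax(0, t - params$detect_lag)
  if (engine == "ode") {
    times <- sort(unique(c(0, ts)))
    sol <- ode_solve(params, times, rtol = 1e-10, atol = 1e-40)
    idx <- match(ts, sol[, "time"])
    out <- cbind(omega1 = sol[idx, "H1"], omega2 = sol[idx, "H2"])
  } else {
    t_max <- max(1, ceiling(max(ts)))
    gr <- expected_grid(params, t_max)
    haz1 <- params$alpha[3] * gr$uI[, 3]
    haz2 <- params$beta[4] * gr$uJ[, 4]
    H1 <- c(0, cumsum((haz1[-1] + haz1[-length(haz1)]) / 2))
    H2 <- c(0, cumsum((haz2[-1] + haz2[-length(haz2)]) / 2))
    out <- cbind(omega1 = stats::approx(gr$t, H1, xout = ts)$y,
                 omega2 = stats::approx(gr$t, H2, xout = ts)$y)
  }
  rownames(out) <- NULL
  out
}

#' Per-age-group tumour-onset probabilities
#'
#' For each age group `(t_{j-1}, t_j]` computes the pathway-specific
#' first-onset probabilities `Q1`, `Q2`, their inclusion-exclusion
#' combination `QT = Q1 + Q2 - Q1*Q2`, the additive small-probability
#' approximation `Q1 + Q2`, and (when the table carries persons at risk)
#' the expected case counts `tau = n * QT`.
#'
#' @param params a [colon_params()] object.
#' @param table an [incidence_table()] (or data.frame with `age_lo`,
#'   `age_hi` in years, optionally `n`).
#' @param engine see [cumulative_intensity()].
#' @return A `data.frame` of class `tumor_risk` with one row per age group.
#' @export
age_group_probabilities <- function(params, table, engine = c("ode", "grid")) {
  engine <- match.arg(engine)
  if (is.unsorted(table$age_lo) || any(table$age_hi <= table$age_lo))
    stop("age group boundaries must be ordered", call. = FALSE)
  lo <- years_to_units(table$age_lo, params)
  hi <- years_to_units(table$age_hi, params)
  om <- cumulative_intensity(params, c(lo, hi), engine = engine)
  m <- nrow(table)
  om_lo <- om[seq_len(m), , drop = FALSE]
  om_hi <- om[m + seq_len(m), , drop = FALSE]
  Q1 <- exp(-om_lo[, 1]) - exp(-om_hi[, 1])
  Q2 <- exp(-om_lo[, 2]) - exp(-om_hi[, 2])
  out <- data.frame(age_lo = table$age_lo, age_hi = table$age_hi,
                    Q1 = Q1, Q2 = Q2,
                    QT = Q1 + Q2 - Q1 * Q2,
                    QT_additive = Q1 + Q2)
  if (!is.null(table$n)) out$tau <- table$n * out$QT
  class(out) <- c("tumor_risk", "data.frame")
  out
}

#' Expected case counts per age group
#'
#' `tau_j = n_j * Q_T(j)`: the Poisson mean of the observed case count in
#' group `j` given `n_j` persons at risk.
#'
#' @inheritParams age_group_probabilities
#' @return Numeric vector of expected cases, one per group.
#' @export
expected_cases <- function(params, table, engine = c("ode", "grid")) {
  table <- validate_incidence_table(as.data.frame(table))
  risk <- age_group_probabilities(params, table, engine = engine)
  table$n * risk$QT
}

#' Poisson log-likelihood of an incidence table
#'
#' `sum_j [ y_j log(tau_j) - tau_j - log(y_j!) ]`.  A group with `tau_j = 0`
#' but `y_j > 0` has likelihood zero; the function returns `-Inf` with a
#' warning.
#'
#' @param y observed case counts (or an [incidence_table()]).
#' @param tau Poisson means, same length.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(y, tau) {
  if (inherits(y, "incidence_table") || is.data.frame(y)) y <- y$y
  if (length(y) != length(tau)) stop("y and tau lengths differ", call. = FALSE)
  if (length(y) == 0L) return(0)
  if (any(tau < 0)) stop("tau must be nonnegative", call. = FALSE)
  bad <- tau == 0 & y > 0
  if (any(bad)) {
    warning("tau = 0 with positive observed count: log-likelihood is -Inf")
    return(-Inf)
  }
  ok <- tau > 0
  sum(y[ok] * log(tau[ok]) - tau[ok] - lgamma(y[ok] + 1))
}

#' Poisson deviance of an incidence table
#'
#' `Dev = 2 sum_j [ y_j log(y_j / tau_j) - (y_j - tau_j) ]`, the deviance of
#' the Poisson observation model against the saturated model, with the
#' continuity convention `y log(y/tau) = 0` when `y = 0` (a zero-count group
#' contributes `2 tau_j`).
#'
#' @inheritParams poisson_loglik
#' @return Scalar deviance (nonnegative; zero iff `tau = y` on the support).
#' @export
poisson_deviance <- function(y, tau) {
  if (inherits(y, "incidence_table") || is.data.frame(y)) y <- y$y
  if (length(y) != length(tau)) stop("y and tau lengths differ", call. = FALSE)
  if (any(tau < 0)) stop("tau must be nonnegative", call. = FALSE)
  bad <- tau == 0 & y > 0
  if (any(bad)) {
    warning("tau = 0 with positive observed count: deviance is Inf")
    return(Inf)
  }
  term <- ifelse(y > 0, y * log(y / pmax(tau, .Machine$double.xmin)), 0)
  2 * sum(term - (y - tau))
}

#' Akaike and Bayesian information criteria from a deviance
#'
#' `AIC = Dev + 2p`, `BIC = Dev + p log(n_points)`.  The free-parameter count
#' `p` and the sample-size convention `n_points` are reported back so that
#' alternative conventions can be recomputed from the same deviance.
#'
#' @param dev model deviance.
#' @param p number of free parameters estimated.
#' @param n_points number of data points (age groups).
#' @return Named list with `AIC`, `BIC`, `dev`, `p`, `n_points`.
#' @export
information_criteria <- function(dev, p, n_points) {
  stopifnot(p >= 0, n_points >= 1)
  list(AIC = dev + 2 * p, BIC = dev + p * log(n_points),
       dev = dev, p = p, n_points = n_points)
}

#' Probability density of time to first tumour
#'
#' Discrete first-onset density of the combined tumour process,
#' `f(t) = exp(-omega_1(t) - omega_2(t)) * d(omega_1 + omega_2)/dt`,
#' evaluated on a grid of ages.  Its integral up to the grid end equals one
#' minus the survivor probability, hence is at most one.
#'
#' @param params a [colon_params()] object.
#' @param age_years increasing grid of ages (years).
#' @param engine see [cumulative_intensity()].
#' @return `data.frame` with `age`, the cumulative intensities, the survivor
#'   probability and `density` (per year).
#' @export
time_to_tumor_density <- function(params, age_years,
                                  engine = c("ode", "grid")) {
  engine <- match.arg(engine)
  t_units <- years_to_units(age_years, params)
  om <- cumulative_intensity(params, t_units, engine = engine)
  surv <- exp(-om[, 1] - om[, 2])
  # hazard at t is the integrand of omega at the lagged time
  ts <- pmax(0, t_units - params$detect_lag)
  u <- if (engine == "ode") expected_numbers_ode(params, ts)
       else {
         gr <- expected_grid(params, max(1, ceiling(max(ts))))
         list(uI = cbind(NA, NA, stats::approx(gr$t, gr$uI[, 3], ts)$y),
              uJ = cbind(NA, NA, NA, stats::approx(gr$t, gr$uJ[, 4], ts)$y))
       }
  haz_unit <- params$alpha[3] * u$uI[, 3] + params$beta[4] * u$uJ[, 4]
  per_year <- 12 / params$dt_months
  data.frame(age = age_years, omega1 = om[, 1], omega2 = om[, 2],
             survivor = surv, density = surv * haz_unit * per_year)
}
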