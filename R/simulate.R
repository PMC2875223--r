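# Exact forward simulation of the two-pathway birth-death-mutation process.
#
# Over one step (t, t+1]:
#   initiations      M0_I ~ Poisson(lambda_I),  M0_J ~ Poisson(lambda_J)
#   births/deaths    (B_l, D_l) ~ Multinomial(I_l(t); b_l(t), d_l(t), rest)
#   stage mutations  M_l ~ Poisson(I_l(t) alpha_l)     (asymmetric: the
#                    mother cell stays in stage l)
# and the accounting identity
#   I_l(t+1) = I_l(t) + B_l - D_l + M_{l-1}   (M_0 := M0_I)
# holds exactly (same for the J pathway).  The draw order is fixed and
# documented so a seeded run is reproducible: initiations (I then J), then
# per-stage multinomials low to high stage (I then J), then per-stage
# mutation Poissons low to high stage (I then J), then tumour seeds.
#
# Tumour onset uses thinning on the grid: tumour seeds founded during step
# (s, s+1] are Poisson with mean equal to the trapezoid of the founding
# intensity (alpha_3 I_3 for CIN, beta_4 J_4 for MSI) over the step, and a
# seed founded in step s becomes detectable at time s + 1 + detect_lag --
# never within its founding step.  This makes the realised cumulative
# intensity of the simulation exactly the trapezoid quadrature used by
# cumulative_intensity().

# binomial/Poisson draws that stay exact for ordinary sizes and switch to a
# rounded-normal approximation only when the exact samplers would lose
# integer resolution anyway
rbinom_safe <- function(n, size, prob) {
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  out <- numeric(n)
  big <- size * prob * (1 - prob) > 1e9
  if (any(big)) {
    mu <- size[big] * prob[big]
    out[big] <- pmax(0, round(stats::rnorm(sum(big), mu,
                                           sqrt(mu * (1 - prob[big])))))
  }
  if (any(!big))
    out[!big] <- stats::rbinom(sum(!big), size[!big], prob[!big])
  pmin(out, size)
}

rpois_safe <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  out <- numeric(n)
  big <- lambda > 1e9
  if (any(big))
    out[big] <- pmax(0, round(stats::rnorm(sum(big), lambda[big],
                                           sqrt(lambda[big]))))
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  out
}

# vectorised multinomial (B, D) over replicates for one stage
draw_birth_death <- function(size, pb, pd) {
  if (pb + pd > 1)
    stop("stage birth + death probability exceeds 1 per time unit",
         call. = FALSE)
  B <- rbinom_safe(length(size), size, pb)
  D <- rbinom_safe(length(size), size - B,
                   if (pb < 1) pd / (1 - pb) else 0)
  cbind(B = B, D = D)
}

#' One forward step of the stochastic system
#'
#' Draws all transition counts for the interval `(t, t + 1]` and advances the
#' population state by the exact accounting identity.  Uses the current R
#' random number generator state.
#'
#' @param state list with elements `t` (time, model units), `I` (integer
#'   counts, CIN stages 1..3) and `J` (integer counts, MSI stages 1..4).
#' @param params a [colon_params()] object.
#' @return List with the advanced `state` and the `counts` of the step:
#'   initiations `M0_I`, `M0_J`, per-stage births `B_I`, `B_J`, deaths `D_I`,
#'   `D_J` and mutations `M_I`, `M_J`.
#' @export
simulate_step <- function(state, params) {
  r <- stage_rates(params, state$t)
  check <- c(r$b_I + r$d_I, r$b_J + r$d_J)
  if (any(check > 1)) {
    off <- which.max(check)
    lab <- c(paste0("I", 1:3), paste0("J", 1:4))[off]
    stop("stage ", lab, ": (b + d) * dt exceeds 1; reconfigure dt_months",
         call. = FALSE)
  }
  M0_I <- rpois_safe(1, r$lambda_I)
  M0_J <- rpois_safe(1, r$lambda_J)
  BD_I <- vapply(1:3, function(l)
    draw_birth_death(state$I[l], r$b_I[l], r$d_I[l])[1, ], numeric(2))
  BD_J <- vapply(1:4, function(rr)
    draw_birth_death(state$J[rr], r$b_J[rr], r$d_J[rr])[1, ], numeric(2))
  M_I <- rpois_safe(3, state$I * r$alpha)
  M_J <- rpois_safe(4, state$J * r$beta)
  newI <- state$I + BD_I[1, ] - BD_I[2, ] + c(M0_I, M_I[1:2])
  newJ <- state$J + BD_J[1, ] - BD_J[2, ] + c(M0_J, M_J[1:3])
  list(state = list(t = state$t + 1, I = newI, J = newJ),
       counts = list(M0_I = M0_I, M0_J = M0_J,
                     B_I = BD_I[1, ], D_I = BD_I[2, ], M_I = M_I,
                     B_J = BD_J[1, ], D_J = BD_J[2, ], M_J = M_J))
}

#' Simulate a full trajectory of the staging and transition variables
#'
#' Repeated [simulate_step()] from the all-zero initial state (a normal
#' individual at risk at `t0 = 0`).
#'
#' @param params a [colon_params()] object.
#' @param t_max final time (model units, positive integer).
#' @param seed optional integer seed for reproducibility.
#' @return A `colon_trajectory`: list with `t` (0..t_max), `states` (matrix
#'   of compartment counts, one row per time), `counts` (matrix of
#'   transition counts, one row per step), the `params` snapshot and `seed`.
#' @export
simulate_trajectory <- function(params, t_max, seed = NULL) {
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_max <- as.integer(t_max)
  state <- list(t = 0, I = numeric(3), J = numeric(4))
  states <- matrix(0, nrow = t_max + 1L, ncol = 7,
                   dimnames = list(NULL, c(paste0("I", 1:3), paste0("J", 1:4))))
  cnames <- c("M0_I", "M0_J", paste0("B_I", 1:3), paste0("D_I", 1:3),
              paste0("M_I", 1:3), paste0("B_J", 1:4), paste0("D_J", 1:4),
              paste0("M_J", 1:4))
  counts <- matrix(0, nrow = t_max, ncol = length(cnames),
                   dimnames = list(NULL, cnames))
  for (i in seq_len(t_max)) {
    step <- simulate_step(state, params)
    state <- step$state
    states[i + 1L, ] <- c(state$I, state$J)
    cc <- step$counts
    counts[i, ] <- c(cc$M0_I, cc$M0_J, cc$B_I, cc$D_I, cc$M_I,
                     cc$B_J, cc$D_J, cc$M_J)
  }
  structure(list(t = 0:t_max, states = states, counts = counts,
                 params = params, seed = seed),
            class = "colon_trajectory")
}

#' @export
print.colon_trajectory <- function(x, ...) {
  cat("Stochastic trajectory over", max(x$t), "time unit(s)\n")
  cat("final state:", paste(colnames(x$states),
                            x$states[nrow(x$states), ], collapse = ", "), "\n")
  invisible(x)
}

#' Export a trajectory to tidy CSV
#'
#' One row per (time, variable) for the states and per (step, variable) for
#' the transition counts.
#'
#' @param traj a `colon_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  st <- data.frame(t = rep(traj$t, ncol(traj$states)),
                   variable = rep(colnames(traj$states), each = length(traj$t)),
                   value = as.vector(traj$states), kind = "state")
  tstep <- traj$t[-1]
  ct <- data.frame(t = rep(tstep, ncol(traj$counts)),
                   variable = rep(colnames(traj$counts), each = length(tstep)),
                   value = as.vector(traj$counts), kind = "transition")
  utils::write.csv(rbind(st, ct), path, row.names = FALSE)
  invisible(path)
}

# Exact one-step transition of a linear birth-death process: over one unit
# of time, each of n cells leaves a clone that is extinct with probability
# alpha_e, else geometric; the population update is binomial survivors plus
# negative-binomial extra offspring.  Exact in distribution for constant
# rates; with the slow growth-limiting decay the step uses the integrated
# net growth, which keeps the step mean exact.
draw_bd_exact <- function(n, b, d, gbar) {
  if (b == 0 && d == 0 && gbar == 0) return(n)
  E <- exp(gbar)
  if (abs(gbar) < 1e-12) {
    alpha_e <- eta <- b / (1 + b)
  } else {
    alpha_e <- pmin(pmax(d * (E - 1) / (b * E - d), 0), 1)
    eta <- pmin(pmax(b * (E - 1) / (b * E - d), 0), 1)
  }
  S <- rbinom_safe(length(n), n, 1 - alpha_e)
  extra <- numeric(length(n))
  pos <- S > 0 & eta > 0
  if (any(pos))
    extra[pos] <- stats::rnbinom(sum(pos), size = S[pos], prob = 1 - eta)
  S + extra
}

# Mean-exact one-step inflow intensities for the exact scheme: the one-step
# mean map of a pathway is the matrix exponential of the augmented cascade
# matrix (net growth on the diagonal, mutation rates below it, immigration
# in the last column acting on a constant source).  The diagonal is realised
# by the exact birth-death draw; everything off-diagonal -- mutant inflow
# including multi-hop chains and within-step growth of newly arrived cells
# -- enters a Poisson draw with the expm off-diagonal weights.
step_mean_map <- function(lambda, mut, gbar) {
  k <- length(gbar)
  M <- matrix(0, k + 1, k + 1)
  diag(M)[seq_len(k)] <- gbar
  for (l in seq_len(k)[-1]) M[l, l - 1] <- mut[l - 1]
  M[1, k + 1] <- lambda
  as.matrix(Matrix::expm(M))
}

# Vectorised ensemble simulation over many independent replicates.
#
# Two schemes: "euler" draws the unit-step multinomial/Poisson transition
# law (the printed transition distributions; used for data augmentation and
# for moment checks of that law); "exact" samples the continuous-time
# branching process -- exact birth-death transitions plus mean-exact mutant
# inflow -- so that ensemble means match the expected-number ODEs to within
# Monte-Carlo error (double mutations within one step, of relative order
# alpha^2, are the only neglected term).
#
# Returns compartment counts at probe times, the realised (lagged, trapezoid)
# cumulative tumour intensity path per replicate, each replicate's first
# tumour detection time, and per-replicate sums of transition counts and
# exposures (the sufficient statistics used by the data-augmentation step;
# "euler" scheme only).
simulate_cohort <- function(params, t_max, n_rep, probe_times = integer(0),
                            tumors = FALSE, omega_paths = FALSE,
                            stats = FALSE, scheme = c("euler", "exact"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  if (stats && scheme != "euler")
    stop("transition-count statistics require the euler scheme",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_max <- as.integer(t_max)
  lag <- as.integer(round(params$detect_lag))
  I <- matrix(0, n_rep, 3)
  J <- matrix(0, n_rep, 4)
  probes <- vector("list", length(probe_times))
  names(probes) <- as.character(probe_times)
  if ("0" %in% names(probes)) probes[["0"]] <- cbind(I, J)
  omega_path1 <- omega_path2 <- if (omega_paths)
    matrix(0, n_rep, t_max + 1L) else NULL
  first_tumor <- first_tumor1 <- first_tumor2 <- rep(Inf, n_rep)
  if (stats) {
    sum_M0 <- matrix(0, n_rep, 2,
                     dimnames = list(NULL, c("M0_I", "M0_J")))
    sum_M_I <- matrix(0, n_rep, 2)    # I1->I2, I2->I3
    sum_M_J <- matrix(0, n_rep, 3)    # J1->J2 .. J3->J4
    sum_B <- matrix(0, n_rep, 4, dimnames = list(NULL,
                    c("I2", "I3", "J3", "J4")))
    sum_D <- sum_B
    expo_I <- matrix(0, n_rep, 3)     # sum_s I_l(s)
    expo_J <- matrix(0, n_rep, 4)
    expo_decay <- matrix(0, n_rep, 2, dimnames = list(NULL,
                         c("I2", "J3")))  # decay-weighted exposures
  }
  haz1_pre <- params$alpha[3] * I[, 3]
  haz2_pre <- params$beta[4] * J[, 4]
  g0 <- proliferation_rates(params)
  # integrated net growth of a decay stage over (s, s+1]
  gbar_decay <- function(b, d, delta, s) {
    if (delta > 0) b * (exp(-delta * s) - exp(-delta * (s + 1))) / delta - d
    else b - d
  }
  for (s in 0:(t_max - 1L)) {
    r <- stage_rates(params, s)
    if (stats) {
      expo_I <- expo_I + I
      expo_J <- expo_J + J
      expo_decay[, 1] <- expo_decay[, 1] + I[, 2] * exp(-params$delta1 * s)
      expo_decay[, 2] <- expo_decay[, 2] + J[, 3] * exp(-params$delta2 * s)
    }
    if (scheme == "euler") {
      M0_I <- rpois_safe(n_rep, rep(r$lambda_I, n_rep))
      M0_J <- rpois_safe(n_rep, rep(r$lambda_J, n_rep))
      B1 <- draw_birth_death(I[, 1], r$b_I[1], r$d_I[1])
      B2 <- draw_birth_death(I[, 2], r$b_I[2], r$d_I[2])
      B3 <- draw_birth_death(I[, 3], r$b_I[3], r$d_I[3])
      C1 <- draw_birth_death(J[, 1], r$b_J[1], r$d_J[1])
      C2 <- draw_birth_death(J[, 2], r$b_J[2], r$d_J[2])
      C3 <- draw_birth_death(J[, 3], r$b_J[3], r$d_J[3])
      C4 <- draw_birth_death(J[, 4], r$b_J[4], r$d_J[4])
      MI <- cbind(rpois_safe(n_rep, I[, 1] * r$alpha[1]),
                  rpois_safe(n_rep, I[, 2] * r$alpha[2]))
      MJ <- cbind(rpois_safe(n_rep, J[, 1] * r$beta[1]),
                  rpois_safe(n_rep, J[, 2] * r$beta[2]),
                  rpois_safe(n_rep, J[, 3] * r$beta[3]))
      I <- I + cbind(B1[, 1] - B1[, 2] + M0_I,
                     B2[, 1] - B2[, 2] + MI[, 1],
                     B3[, 1] - B3[, 2] + MI[, 2])
      J <- J + cbind(C1[, 1] - C1[, 2] + M0_J,
                     C2[, 1] - C2[, 2] + MJ[, 1],
                     C3[, 1] - C3[, 2] + MJ[, 2],
                     C4[, 1] - C4[, 2] + MJ[, 3])
      if (stats) {
        sum_M0 <- sum_M0 + cbind(M0_I, M0_J)
        sum_M_I <- sum_M_I + MI
        sum_M_J <- sum_M_J + MJ
        sum_B <- sum_B + cbind(B2[, 1], B3[, 1], C3[, 1], C4[, 1])
        sum_D <- sum_D + cbind(B2[, 2], B3[, 2], C3[, 2], C4[, 2])
      }
    } else {
      gI <- c(g0$gamma_I[1],
              gbar_decay(params$b_I[2], params$d_I[2], params$delta1, s),
              g0$gamma_I[3])
      gJ <- c(g0$gamma_J[1], g0$gamma_J[2],
              gbar_decay(params$b_J[3], params$d_J[3], params$delta2, s),
              g0$gamma_J[4])
      b_mid <- stage_rates(params, s + 0.5)
      PhiI <- step_mean_map(params$lambda_I, params$alpha[1:2], gI)
      PhiJ <- step_mean_map(params$lambda_J, params$beta[1:3], gJ)
      inflow_mean <- function(Phi, X, l) {
        mu <- Phi[l, ncol(Phi)]                     # immigration chain
        for (k in seq_len(l - 1)) mu <- mu + Phi[l, k] * X[, k]
        mu
      }
      I <- cbind(
        draw_bd_exact(I[, 1], b_mid$b_I[1], params$d_I[1], gI[1]) +
          rpois_safe(n_rep, inflow_mean(PhiI, I, 1)),
        draw_bd_exact(I[, 2], b_mid$b_I[2], params$d_I[2], gI[2]) +
          rpois_safe(n_rep, inflow_mean(PhiI, I, 2)),
        draw_bd_exact(I[, 3], b_mid$b_I[3], params$d_I[3], gI[3]) +
          rpois_safe(n_rep, inflow_mean(PhiI, I, 3)))
      J <- cbind(
        draw_bd_exact(J[, 1], b_mid$b_J[1], params$d_J[1], gJ[1]) +
          rpois_safe(n_rep, inflow_mean(PhiJ, J, 1)),
        draw_bd_exact(J[, 2], b_mid$b_J[2], params$d_J[2], gJ[2]) +
          rpois_safe(n_rep, inflow_mean(PhiJ, J, 2)),
        draw_bd_exact(J[, 3], b_mid$b_J[3], params$d_J[3], gJ[3]) +
          rpois_safe(n_rep, inflow_mean(PhiJ, J, 3)),
        draw_bd_exact(J[, 4], b_mid$b_J[4], params$d_J[4], gJ[4]) +
          rpois_safe(n_rep, inflow_mean(PhiJ, J, 4)))
    }
    haz1_post <- params$alpha[3] * I[, 3]
    haz2_post <- params$beta[4] * J[, 4]
    step1 <- (haz1_pre + haz1_post) / 2
    step2 <- (haz2_pre + haz2_post) / 2
    det <- s + 1L + lag    # seeds of step s detectable from here on
    if (tumors && det <= t_max) {
      hit1 <- rpois_safe(n_rep, step1) > 0
      hit2 <- rpois_safe(n_rep, step2) > 0
      first_tumor1[hit1 & det < first_tumor1] <- det
      first_tumor2[hit2 & det < first_tumor2] <- det
      first_tumor <- pmin(first_tumor1, first_tumor2)
    }
    if (omega_paths && det <= t_max) {
      omega_path1[, det + 1L] <- step1
      omega_path2[, det + 1L] <- step2
    }
    haz1_pre <- haz1_post
    haz2_pre <- haz2_post
    key <- as.character(s + 1L)
    if (key %in% names(probes)) probes[[key]] <- cbind(I, J)
  }
  if (omega_paths) {
    omega_path1 <- t(apply(omega_path1, 1, cumsum))
    omega_path2 <- t(apply(omega_path2, 1, cumsum))
  }
  out <- list(I = I, J = J, probes = probes,
              omega_path1 = omega_path1, omega_path2 = omega_path2,
              first_tumor = first_tumor, first_tumor1 = first_tumor1,
              first_tumor2 = first_tumor2, t_max = t_max)
  if (stats)
    out$stats <- list(M0 = sum_M0, M_I = sum_M_I, M_J = sum_M_J,
                      B = sum_B, D = sum_D,
                      expo_I = expo_I, expo_J = expo_J,
                      expo_decay = expo_decay, steps = t_max)
  out
}

#' Simulate tumour-onset events along a trajectory
#'
#' Given a simulated trajectory of initiated-cell counts, draws the
#' detectable-tumour counting processes of both pathways: the number of
#' tumours founded during step `(s, s+1]` is Poisson with mean equal to the
#' trapezoid of the founding intensity (`alpha_3 I_3` for CIN,
#' `beta_4 J_4` for MSI) over the step; a tumour founded in step `s` becomes
#' detectable at `s + 1 + detect_lag`, never within its founding step.
#'
#' @param traj a `colon_trajectory` from [simulate_trajectory()].
#' @param params a [colon_params()] object (defaults to the trajectory's
#'   snapshot).
#' @param seed optional integer seed.
#' @return `data.frame` with columns `t`, `new1`, `new2` (tumours becoming
#'   detectable at `t`, by pathway) and cumulative totals `T1`, `T2`.
#' @export
simulate_tumor_onset <- function(traj, params = traj$params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_max <- max(traj$t)
  lag <- as.integer(round(params$detect_lag))
  int1 <- params$alpha[3] * traj$states[, "I3"]
  int2 <- params$beta[4] * traj$states[, "J4"]
  mean1 <- (int1[-1] + int1[-length(int1)]) / 2
  mean2 <- (int2[-1] + int2[-length(int2)]) / 2
  founded1 <- rpois_safe(t_max, mean1)
  founded2 <- rpois_safe(t_max, mean2)
  new1 <- new2 <- numeric(t_max + 1L)
  det <- seq_len(t_max) + lag          # step s = 0..t_max-1 detected at s+1+lag
  ok <- det <= t_max
  if (any(ok)) {
    new1[det[ok] + 1L] <- founded1[ok]
    new2[det[ok] + 1L] <- founded2[ok]
  }
  data.frame(t = traj$t, new1 = new1, new2 = new2,
             T1 = cumsum(new1), T2 = cumsum(new2))
}

#' Generate a synthetic age-grouped incidence table
#'
#' Computes the per-person onset probabilities `Q_T(j)` from the model and
#' draws `y_j ~ Binomial(n_j, Q_T(j))` independently across age groups.
#' The returned table records the generating parameters and seed as
#' attributes (provenance).
#'
#' @param params a [colon_params()] object.
#' @param risk_schedule data.frame with `age_lo`, `age_hi` (years) and `n`
#'   persons at risk per group.
#' @param seed optional integer seed.
#' @param engine see [cumulative_intensity()].
#' @return An [incidence_table()] with simulated `y`.
#' @export
simulate_incidence <- function(params, risk_schedule, seed = NULL,
                               engine = c("ode", "grid")) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  risk <- age_group_probabilities(params, risk_schedule, engine = engine)
  if (any(risk$QT < 0 | risk$QT > 1))
    stop("Q_T outside [0, 1]", call. = FALSE)
  y <- rbinom_safe(nrow(risk), risk_schedule$n, risk$QT)
  tab <- incidence_table(risk_schedule$age_lo, risk_schedule$age_hi,
                         risk_schedule$n, y)
  attr(tab, "params") <- params
  attr(tab, "seed") <- seed
  tab
}
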