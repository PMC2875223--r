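test_that("a step from the all-zero state only contains initiations", {
  p <- small_params()
  set.seed(11)
  out <- simulate_step(list(t = 0, I = numeric(3), J = numeric(4)), p)
  expect_true(all(out$counts$B_I == 0) && all(out$counts$D_I == 0))
  expect_true(all(out$counts$B_J == 0) && all(out$counts$D_J == 0))
  expect_true(all(out$counts$M_I == 0) && all(out$counts$M_J == 0))
  expect_equal(out$state$I, c(out$counts$M0_I, 0, 0))
  expect_equal(out$state$J, c(out$counts$M0_J, 0, 0, 0))
})

test_that("the accounting identity holds exactly along whole trajectories", {
  p <- default_params()
  traj <- simulate_trajectory(p, t_max = 120, seed = 7)
  cn <- traj$counts
  dI <- diff(traj$states[, 1:3])
  dJ <- diff(traj$states[, 4:7])
  expect_equal(dI[, 1], cn[, "B_I1"] - cn[, "D_I1"] + cn[, "M0_I"])
  expect_equal(dI[, 2], cn[, "B_I2"] - cn[, "D_I2"] + cn[, "M_I1"])
  expect_equal(dI[, 3], cn[, "B_I3"] - cn[, "D_I3"] + cn[, "M_I2"])
  expect_equal(dJ[, 1], cn[, "B_J1"] - cn[, "D_J1"] + cn[, "M0_J"])
  expect_equal(dJ[, 4], cn[, "B_J4"] - cn[, "D_J4"] + cn[, "M_J3"])
  expect_true(all(traj$states >= 0))
})

test_that("identical seed and parameters reproduce a trajectory exactly", {
  p <- default_params()
  t1 <- simulate_trajectory(p, 60, seed = 42)
  t2 <- simulate_trajectory(p, 60, seed = 42)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$counts, t2$counts)
})

test_that("zero initiation gives the identically zero trajectory", {
  traj <- simulate_trajectory(null_params(), 30, seed = 1)
  expect_true(all(traj$states == 0) && all(traj$counts == 0))
})

test_that("one-step birth and death draws match their binomial moments", {
  set.seed(301)
  n <- 1e5
  bd <- colonmsce:::draw_birth_death(rep(1000, n), 0.0074, 0.0038)
  for (case in list(list(x = bd[, 1], p = 0.0074, mu = 7.4),
                    list(x = bd[, 2], p = 0.0038, mu = 3.8))) {
    se <- sqrt(1000 * case$p * (1 - case$p) / n)
    expect_lt(abs(mean(case$x) - case$mu), 3 * se)
  }
})

test_that("one-step compartment noise has the Poisson + multinomial variance", {
  # delta I2 = B2 - D2 + M1 with I1, I2 fixed: Var = I2 (pb(1-pb) + pd(1-pd)
  # + 2 pb pd) + I1 alpha1  (independent multinomial and Poisson pieces)
  p <- small_params()
  I1 <- 5000; I2 <- 1000
  pb <- p$b_I[2]; pd <- p$d_I[2]; a1 <- p$alpha[1]
  set.seed(302)
  n <- 1e5
  bd <- colonmsce:::draw_birth_death(rep(I2, n), pb, pd)
  m1 <- rpois(n, I1 * a1)
  delta <- bd[, 1] - bd[, 2] + m1
  v_theory <- I2 * (pb * (1 - pb) + pd * (1 - pd) + 2 * pb * pd) + I1 * a1
  v_emp <- var(delta)
  m4 <- mean((delta - mean(delta))^4)
  se_var <- sqrt((m4 - v_emp^2) / n)
  expect_lt(abs(v_emp - v_theory), 3 * se_var)
  expect_lt(abs(mean(delta) - (I2 * (pb - pd) + I1 * a1)),
            3 * sqrt(v_theory / n))
})

test_that("ensemble means match the expected numbers", {
  p <- default_params()
  probe <- c(100, 200, 280)
  sim <- colonmsce:::simulate_cohort(p, 280, n_rep = 2000,
                                     probe_times = probe, scheme = "exact",
                                     seed = 21)
  u <- expected_numbers_ode(p, probe)
  for (k in seq_along(probe)) {
    st <- sim$probes[[as.character(probe[k])]]
    for (j in 1:3) {
      se <- stats::sd(st[, j]) / sqrt(nrow(st))
      expect_lt(abs(mean(st[, j]) - u$uI[k, j]), 3 * se + 1e-9)
    }
    for (j in 1:4) {
      se <- stats::sd(st[, 3 + j]) / sqrt(nrow(st))
      expect_lt(abs(mean(st[, 3 + j]) - u$uJ[k, j]), 3 * se + 1e-9)
    }
  }
})

test_that("tumour onset never occurs without terminal mutation pressure", {
  p <- small_params(alpha = c(2e-3, 5e-3, 0), beta = c(1e-3, 2e-3, 4e-3, 0))
  traj <- simulate_trajectory(p, 100, seed = 3)
  on <- simulate_tumor_onset(traj, seed = 4)
  expect_true(all(on$T1 == 0) && all(on$T2 == 0))
})

test_that("no tumour is detected in the step of its founding transition", {
  # constructed trajectory with massive last-stage populations from t = 0:
  # with detect_lag = 1 the earliest detection time is step + 2
  p <- small_params(alpha = c(0, 0, 0.5))
  traj <- list(t = 0:5,
               states = matrix(1e4, 6, 7,
                               dimnames = list(NULL, c(paste0("I", 1:3),
                                                       paste0("J", 1:4)))),
               params = p)
  class(traj) <- "colon_trajectory"
  on <- simulate_tumor_onset(traj, seed = 5)
  expect_equal(on$new1[1:2], c(0, 0))
  expect_gt(sum(on$new1), 0)
})

test_that("first-onset fractions agree with the competing-Poisson survivor", {
  p <- default_params()
  n <- 3000
  sim <- colonmsce:::simulate_cohort(p, 340, n_rep = n, tumors = TRUE,
                                     scheme = "exact", seed = 99)
  om <- cumulative_intensity(p, c(240, 300, 340), engine = "grid")
  for (k in 1:3) {
    tt <- c(240, 300, 340)[k]
    p_mc <- mean(sim$first_tumor <= tt)
    p_th <- 1 - exp(-om[k, 1] - om[k, 2])
    se <- sqrt(p_th * (1 - p_th) / n)
    expect_lt(abs(p_mc - p_th), 3 * se + 0.003)
  }
})

test_that("synthetic incidence tables have binomial means and provenance", {
  p <- small_params()
  sched <- small_schedule()
  tau <- expected_cases(p, cbind(sched, y = 0))
  reps <- vapply(1:200, function(s) simulate_incidence(p, sched, seed = s)$y,
                 numeric(nrow(sched)))
  risk <- age_group_probabilities(p, sched)
  for (j in seq_len(nrow(sched))) {
    se <- sqrt(sched$n[j] * risk$QT[j] * (1 - risk$QT[j]) / 200)
    expect_lt(abs(mean(reps[j, ]) - tau[j]), 3 * se)
  }
  tab <- simulate_incidence(p, sched, seed = 1)
  expect_s3_class(tab, "incidence_table")
  expect_identical(attr(tab, "seed"), 1)
  # zero persons at risk cannot yield cases
  sched0 <- sched; sched0$n[2] <- 0
  expect_equal(simulate_incidence(p, sched0, seed = 2)$y[2], 0)
  # zero initiation cannot yield cases
  expect_true(all(simulate_incidence(null_params(), sched, seed = 3)$y == 0))
})

test_that("trajectories export to tidy CSV and read back consistently", {
  p <- small_params()
  traj <- simulate_trajectory(p, 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  tidy <- utils::read.csv(path)
  expect_setequal(unique(tidy$kind), c("state", "transition"))
  i3 <- tidy[tidy$variable == "I3" & tidy$kind == "state", ]
  expect_equal(i3$value[order(i3$t)], unname(traj$states[, "I3"]))
})
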