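test_that("scenario derives its mixture, variance and bias quantities", {
  sc <- scenario_config(ARE = 1, ARE1 = 1.5, pi = 0.5, gamma2 = 0,
                        alpha = 0.25)
  expect_equal(sc$ARE2, 0.5)          # (1 - 0.5*1.5) / 0.5
  expect_equal(sc$zeta, 0.5)
  expect_equal(sc$phi_alpha, 0.5)     # (0 - (-2)) * 0.25
  expect_equal(sc$omega_sq, 0.75)     # nu_sq - tau1_sq
  expect_equal(sc$omega0_sq, 15.75)   # sigma0^2 - tau0_sq
  expect_error(scenario_config(pi = 1), "pi")
  expect_error(scenario_config(tau1_sq = 2, nu_sq = 1), "tau1_sq")
  expect_error(scenario_config(n1 = 10, k = 4), "fewer than 4")
})

test_that("bias operation returns projection and generalizability bias", {
  expect_equal(
    biases(scenario_config(gamma1 = -2, gamma2 = 0, alpha = 0.25)),
    c(phi_alpha = 0.5, zeta = 0))
  expect_equal(
    biases(scenario_config(ARE1 = 0.5, ARE = 1))[["zeta"]], -0.5)
  # equal pre/post slopes mean no projection bias at any alpha
  for (a in c(0.25, 0.5, 1)) {
    expect_equal(
      biases(scenario_config(gamma1 = -2, gamma2 = -2,
                             alpha = a))[["phi_alpha"]], 0)
  }
})

test_that("control trajectory is the two-slope line through the offer", {
  sc <- scenario_config(gamma1 = -2, gamma2 = -2)
  expect_equal(control_trajectory(sc, 20, 0), 20)
  expect_equal(control_trajectory(sc, 20, 1) - control_trajectory(sc, 20, -1),
               -4)
  sc2 <- scenario_config(gamma2 = 0)
  expect_equal(control_trajectory(sc2, 20, 2), 20)   # flat post segment
})

test_that("treated-minus-control difference satisfies the offer-time contract", {
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 0.05, 1.5); d <- runif(1, 0.05, 1.5)
    sc <- scenario_config(alpha = a, delta = d,
                          gamma2 = runif(1, -4, 0),
                          gamma3 = runif(1, -3, 0))
    g0 <- rnorm(1, 20, 2); Dl <- rnorm(1, 1, 1)
    # exactly Delta at t = alpha
    expect_equal(treated_trajectory(sc, g0, Dl, a) -
                   control_trajectory(sc, g0, a), Dl, tolerance = 1e-12)
    # no instantaneous jump at offer, and identical to control before it
    expect_equal(treated_trajectory(sc, g0, Dl, 0), g0)
    tneg <- runif(3, -1, 0)
    expect_equal(treated_trajectory(sc, g0, Dl, tneg),
                 control_trajectory(sc, g0, tneg))
    # continuous at the second change point
    eps <- 1e-9
    expect_equal(treated_trajectory(sc, g0, Dl, d - eps),
                 treated_trajectory(sc, g0, Dl, d + eps), tolerance = 1e-6)
  }
})

test_that("late branch of the difference meets its closed-form value at delta", {
  # alpha >= delta: both sides of the change point give
  # control + Delta + (gamma3 - gamma2) * (delta - alpha)
  sc <- scenario_config(alpha = 1, delta = 0.3, gamma2 = -1.5, gamma3 = -1.9)
  g0 <- 20; Dl <- 1.2
  want <- control_trajectory(sc, g0, 0.3) + Dl +
    (sc$gamma3 - sc$gamma2) * (0.3 - 1)
  expect_equal(treated_trajectory(sc, g0, Dl, 0.3), want, tolerance = 1e-9)
  # difference is piecewise linear with its only kink at delta:
  # second differences vanish away from delta
  tt <- seq(0.35, 3, by = 0.05)
  dif <- treated_trajectory(sc, g0, Dl, tt) - control_trajectory(sc, g0, tt)
  expect_equal(diff(dif, differences = 2), rep(0, length(tt) - 2),
               tolerance = 1e-9)
})

test_that("simulated trials split n1 evenly and honour degenerate variances", {
  sc <- scenario_config(n1 = 1000, k = 4)
  set.seed(1)
  tr <- simulate_trials(sc)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$n_treated + tr$n_control, rep(250L, 4))
  # remainder participants go to the first trials
  sc2 <- scenario_config(n1 = 1002, k = 4)
  set.seed(1)
  expect_message(tr2 <- simulate_trials(sc2), "extra")
  expect_equal(sort(tr2$n_treated + tr2$n_control, decreasing = TRUE),
               c(251L, 251L, 250L, 250L))
  # all variance knobs at zero: every trial estimate is exactly ARE1
  sc0 <- scenario_config(n1 = 400, k = 4, ARE1 = 1.5, ARE = 1.2, pi = 0.5,
                         sigma = 0, tau1_sq = 0, nu_sq = 0,
                         sigma0 = 1, tau0_sq = 0)
  set.seed(2)
  tr0 <- simulate_trials(sc0)
  expect_equal(tr0$estimate, rep(1.5, 4), tolerance = 1e-12)
})

test_that("trial estimates are centred on the eligible-stratum effect", {
  sc <- scenario_config(n1 = 200, k = 4, ARE1 = 1.5, ARE = 1, pi = 0.5)
  set.seed(99)
  ests <- replicate(300, mean(simulate_trials(sc)$estimate))
  mcse <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.5), 4 * mcse)
})

test_that("simulated cohorts reproduce the eligibility and effect structure", {
  sc <- scenario_config(n2 = 4000, pi = 0.7, ARE1 = 1.5, ARE = 1)
  set.seed(21)
  ds <- simulate_cohort(sc)
  frac <- mean(ds$eligible)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 4000))
  # observation schedule: counts within range, times within window
  cnt <- table(ds$records$subject_id)
  expect_true(all(cnt >= 1 & cnt <= 8))
  expect_true(all(ds$records$time_years >= -1 & ds$records$time_years <= 3))
})

test_that("noiseless eligible subjects show exactly ARE1 at alpha", {
  sc <- scenario_config(n2 = 50, pi = 0.5, ARE1 = 1.5, ARE = 1,
                        sigma = 0, nu_sq = 0, tau1_sq = 0,
                        sigma0 = 1e-12, tau0_sq = 0, gamma2 = 0)
  set.seed(8)
  ds <- simulate_cohort(sc)
  r <- ds$records
  elig <- ds$eligible[r$subject_id]
  g0 <- sc$Gamma01
  # every eligible record lies exactly on the treated mean curve with
  # Delta = ARE1 ...
  re <- r[elig, ]
  expect_equal(re$adjusted_score,
               treated_trajectory(sc, g0, 1.5, re$time_years),
               tolerance = 1e-9)
  # ... and the value at alpha exceeds the untreated two-slope curve by
  # exactly ARE1, and the projected pre-offer line by ARE1 + phi_alpha
  val <- treated_trajectory(sc, g0, 1.5, sc$alpha)
  expect_equal(val - (g0 + sc$gamma2 * sc$alpha), 1.5, tolerance = 1e-9)
  expect_equal(val - (g0 + sc$gamma1 * sc$alpha), 1.5 + sc$phi_alpha,
               tolerance = 1e-9)
})

test_that("stratum means of the individual effects obey total expectation", {
  sc <- scenario_config(n2 = 20000, pi = 0.6, ARE1 = 1.5, ARE = 1,
                        sigma = 0, obs_range = c(1L, 1L))
  set.seed(31)
  Z <- rbinom(sc$n2, 1, sc$pi)
  Dl <- rnorm(sc$n2, ifelse(Z == 1, sc$ARE1, sc$ARE2), sqrt(sc$nu_sq))
  se1 <- sqrt(sc$nu_sq / sum(Z == 1))
  se2 <- sqrt(sc$nu_sq / sum(Z == 0))
  expect_lt(abs(mean(Dl[Z == 1]) - sc$ARE1), 4 * se1)
  expect_lt(abs(mean(Dl[Z == 0]) - sc$ARE2), 4 * se2)
  expect_lt(abs(mean(Dl) - sc$ARE), 4 * sqrt(var(Dl) / sc$n2))
})

test_that("identical seed and scenario reproduce the study bit for bit", {
  sc <- scenario_config(n2 = 60, n1 = 100, k = 4)
  a <- simulate_study(sc, seed = 77)
  b <- simulate_study(sc, seed = 77)
  expect_identical(a$trials, b$trials)
  expect_identical(a$cohort$records, b$cohort$records)
  expect_identical(a$cohort$eligible, b$cohort$eligible)
  c <- simulate_study(sc, seed = 78)
  expect_false(identical(a$cohort$records, c$cohort$records))
})
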