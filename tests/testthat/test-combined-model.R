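# Two-stratum low-noise cohort: eligible subjects carry effect ARE1_true,
# non-eligible ARE2_true, common slopes; used for identification checks.
two_stratum_cohort <- function(n_subj = 60, ARE1_true = 1.5,
                               ARE2_true = 0.5, phi_true = 0.5,
                               alpha = 0.25, sigma = 0.05, seed = 202) {
  # theta per stratum = stratum effect + projection bias
  set.seed(seed)
  elig <- rep(c(TRUE, FALSE), length.out = n_subj)
  ids <- sprintf("p%03d", seq_len(n_subj))
  recs <- lapply(seq_len(n_subj), function(i) {
    th <- (if (elig[i]) ARE1_true else ARE2_true) + phi_true
    p <- trajectory_params(20, -2, -1.9, delta = 0.3, theta_alpha = th)
    tt <- sort(runif(6, -1, 3))
    data.frame(subject_id = ids[i], time_years = tt,
               adjusted_score = mean_trajectory(tt, p, alpha) +
                 rnorm(1, 0, 0.5) + rnorm(6, 0, sigma))
  })
  cohort_dataset(do.call(rbind, recs),
                 eligible = stats::setNames(elig, ids))
}

test_that("mixture effect is the exact eligibility-weighted average", {
  expect_equal(mixture_effect(1.5, 0.5, 0.5), 1)
  expect_equal(mixture_effect(2, 0, 1), 2)           # pi = 1 -> ARE1
  expect_equal(mixture_effect(rep(3, 5), rep(3, 5), runif(5)), rep(3, 5))
  expect_error(mixture_effect(1:3, 1:2, 0.5), "equal length")
})

test_that("invalid priors and degenerate strata are rejected", {
  ds <- two_stratum_cohort(n_subj = 10)
  expect_error(
    fit_combined_model(ds, 0.25, prior_ARE1 = list(mean = 1, sd = 0)),
    "positive sd")
  all_elig <- ds
  all_elig$eligible[] <- TRUE
  expect_error(
    fit_combined_model(all_elig, 0.25,
                       prior_ARE1 = list(mean = 1, sd = 1)),
    "strata")
  no_flags <- cohort_dataset(ds$records)
  expect_error(
    fit_combined_model(no_flags, 0.25,
                       prior_ARE1 = list(mean = 1, sd = 1)),
    "eligibility")
})

test_that("noiseless identification: point-mass prior pins ARE1, freeing phi and ARE2", {
  ds <- two_stratum_cohort(n_subj = 60, ARE1_true = 1.5, ARE2_true = 0.5,
                           phi_true = 0.5, sigma = 0.05)
  fit <- fit_combined_model(ds, alpha = 0.25,
                            prior_ARE1 = list(mean = 1.5, sd = 1e-3),
                            re_spec = "b0", config = tiny_mcmc(seed = 17))
  s <- fit$summary
  get <- function(p) s[s$param == p, "mean"]
  # prior dominance: ARE1 posterior collapses to the prior mean
  expect_lt(abs(get("ARE1") - 1.5), 0.01)
  # eligible-stratum gap is ARE1 + phi, so phi centres on 0.5
  expect_lt(abs(get("phi_alpha") - 0.5), 0.1)
  # non-eligible gap minus phi identifies ARE2
  expect_lt(abs(get("ARE2") - 0.5), 0.15)
  # mixture: pi ~ 0.5 here, so ARE ~ 1
  expect_lt(abs(get("ARE") - 1), 0.1)
})

test_that("the mixture identity holds exactly on every posterior draw", {
  ds <- two_stratum_cohort(n_subj = 20, sigma = 0.3)
  fit <- fit_combined_model(ds, 0.25, prior_ARE1 = list(mean = 1.5, sd = 0.3),
                            re_spec = "b0",
                            config = tiny_mcmc(seed = 23, iter = 300,
                                               warmup = 150))
  d <- posterior_draws(fit, c("ARE", "ARE1", "ARE2", "pi"))
  expect_equal(d[, "ARE"],
               d[, "pi"] * d[, "ARE1"] + (1 - d[, "pi"]) * d[, "ARE2"],
               tolerance = 1e-12)
})

test_that("eligible proportion posterior matches the Beta-Binomial conjugate", {
  # 70 of 100 eligible with a U(0,1) prior: posterior mean pi = 71/102
  set.seed(91)
  elig <- rep(c(TRUE, FALSE), c(70, 30))
  ids <- sprintf("q%03d", 1:100)
  rec <- data.frame(
    subject_id = rep(ids, each = 3),
    time_years = as.vector(replicate(100, c(-0.5, runif(2, 0.1, 3)))),
    adjusted_score = rnorm(300, 20, 1))
  ds <- cohort_dataset(rec, eligible = stats::setNames(elig, ids))
  fit <- fit_combined_model(ds, 0.25, prior_ARE1 = list(mean = 0, sd = 1),
                            re_spec = "b0",
                            config = tiny_mcmc(seed = 29, iter = 700,
                                               warmup = 200))
  pi_mean <- fit$summary[fit$summary$param == "pi", "mean"]
  pi_draws <- posterior_draws(fit, "pi")
  mcse <- sd(pi_draws) / sqrt(coda::effectiveSize(as.vector(pi_draws)))
  expect_lt(abs(pi_mean - 71 / 102), 3 * mcse + 0.005)
})

test_that("with one stratum and fixed zero bias the model reduces to the cohort fit", {
  ds <- tiny_model_cohort(n_subj = 30, theta = 1, sigma = 0.3,
                          eligible = rep(TRUE, 30))
  cfg <- tiny_mcmc(seed = 41, iter = 600, warmup = 250)
  cof <- fit_cohort_model(ds, 0.25, re_spec = "b0", config = cfg)
  com <- fit_combined_model(ds, 0.25,
                            prior_ARE1 = list(mean = 0, sd = 100),
                            re_spec = "b0", config = cfg, phi_fixed = 0)
  th <- cof$summary[cof$summary$param == "theta_alpha", ]
  a1 <- com$summary[com$summary$param == "ARE1", ]
  # same data, flat prior, no bias term: ARE1 posterior ~ theta posterior
  expect_lt(abs(th$mean - a1$mean), 3 * sqrt(th$sd^2 + a1$sd^2) /
              sqrt(min(th$ess, a1$ess)) + 0.05)
  expect_lt(abs(th$sd - a1$sd) / th$sd, 0.5)
})
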