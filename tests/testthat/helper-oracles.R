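# Independent oracles and small shared fixtures.

# Direct piecewise evaluation of the treated mean trajectory in its natural
# (beta2) parametrization; used as the independent check of the
# reparametrized basis form in mean_trajectory().
mu1_piecewise <- function(t, beta0, beta1, beta2, beta3, delta) {
  ifelse(t < 0, beta0 + beta1 * t,
         ifelse(t < delta, beta0 + beta2 * t,
                beta0 + (beta2 - beta3) * delta + beta3 * t))
}

# Hand inverse-variance (common-effect) pooling.
iv_pool <- function(est, se) {
  w <- 1 / se^2
  list(estimate = sum(w * est) / sum(w), se = sqrt(1 / sum(w)))
}

# Five-criterion trial-eligibility config used across tests.
example_criteria <- function() {
  eligibility_criteria(
    list(field = "age_years", op = "range", args = c(40, 94)),
    list(field = "baseline_score", op = "range", args = c(10, 26)),
    list(field = "diagnosis_code", op = "in_set",
         args = c("alzheimers", "alzheimers_cvd")),
    list(field = "has_caregiver", op = "equals", args = TRUE),
    list(field = "has_other_major_psychiatric_disorder", op = "equals",
         args = FALSE))
}

example_baselines <- function() {
  data.frame(
    subject_id = c("a", "b", "c"),
    age_years = c(50, 95, 60),
    baseline_score = c(20, 20, 27),
    diagnosis_code = c("alzheimers", "alzheimers", "alzheimers_cvd"),
    has_caregiver = c(TRUE, TRUE, TRUE),
    has_other_major_psychiatric_disorder = c(FALSE, FALSE, FALSE))
}

# Small deterministic cohort generated from known trajectory parameters,
# with subject-specific intercepts and near-zero residual noise; used for
# recovery checks.
tiny_model_cohort <- function(n_subj = 40, theta = 1, beta0 = 20,
                              beta1 = -2, beta3 = -1.9, delta = 0.3,
                              alpha = 0.25, sd_b0 = 1, sigma = 0.05,
                              seed = 101, eligible = NULL) {
  set.seed(seed)
  pars <- trajectory_params(beta0, beta1, beta3, delta, theta)
  id <- rep(seq_len(n_subj), each = 6)
  tt <- as.vector(replicate(n_subj, sort(runif(6, -1, 3))))
  b0 <- rnorm(n_subj, 0, sd_b0)
  y <- mean_trajectory(tt, pars, alpha) + b0[id] + rnorm(length(tt), 0, sigma)
  ids <- sprintf("p%03d", seq_len(n_subj))
  rec <- data.frame(subject_id = ids[id], time_years = tt,
                    adjusted_score = y)
  elig <- if (is.null(eligible)) NULL else
    stats::setNames(eligible, ids)
  cohort_dataset(rec, eligible = elig)
}

# Short-chain sampler settings for unit tests.
tiny_mcmc <- function(seed = 11, chains = 2, iter = 500, warmup = 200) {
  mcmc_config(chains = chains, iter = iter, warmup = warmup, seed = seed)
}
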