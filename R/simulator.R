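#' Simulation scenario configuration
#'
#' Defines one scenario of the generative model used to compare the
#' trials-only, cohort-only and combined estimators. The target population
#' splits into a trial-eligible stratum (proportion \code{pi}, itself split
#' into \code{k} trial-specific subsets) and a non-eligible stratum.
#' Individual treatment effects Delta_i are normal around the stratum mean
#' (ARE1 with between-trial spread \code{tau1_sq} and within-subset spread
#' \code{omega_sq} in the eligible stratum; ARE2 with total spread
#' \code{nu_sq} in the non-eligible stratum), and outcomes follow piecewise
#' linear trajectories: slope \code{gamma1} before the offer, \code{gamma2}
#' after the offer had treatment not been offered, and \code{gamma3} beyond
#' the second change point \code{delta} under treatment, with residual SD
#' \code{sigma}.
#'
#' Derived quantities: \code{ARE2 = (ARE - pi * ARE1) / (1 - pi)} (so the
#' generalizability bias \code{zeta = ARE1 - ARE} is the controlled input),
#' \code{omega_sq = nu_sq - tau1_sq}, \code{omega0_sq = sigma0^2 - tau0_sq},
#' projection bias \code{phi_alpha = (gamma2 - gamma1) * alpha}.
#'
#' Defaults are the scenario values of the accompanying simulation study:
#' total trial size 1000 over 4 trials, cohort size 1500, population effect
#' 1 MMSE point at alpha = 0.25 years, eligible proportion 0.7, intercept
#' mean 20 (SD 4), decline -2 points/yr pre-offer, late slope -1.9, second
#' change point 0.3 yr, residual SD 2, Delta variance 1 with between-trial
#' component 0.25.
#'
#' @param n1 Combined size of all trials.
#' @param k Number of trials.
#' @param n2 Cohort size.
#' @param ARE Population-average effect of the treatment offer at alpha.
#' @param ARE1 Average effect in the trial-eligible stratum.
#' @param alpha Evaluation time (years).
#' @param pi Trial-eligible proportion, in (0, 1).
#' @param Gamma0,Gamma01,Gamma02 Mean outcome at offer: population,
#'   eligible-stratum and non-eligible-stratum (all default 20).
#' @param gamma1,gamma2,gamma3 Slopes (score/yr): pre-offer; post-offer
#'   without treatment; post-change-point under treatment.
#' @param delta Second change-point time (years).
#' @param sigma Residual SD.
#' @param sigma0 Total SD of the outcome at offer.
#' @param nu_sq Total variance of Delta_i within each stratum.
#' @param tau1_sq Between-trial variance of the trial-level effects.
#' @param tau0_sq Between-trial variance of the trial-level intercepts.
#' @param obs_range Integer length-2: min and max observations per cohort
#'   subject (count drawn uniformly).
#' @param time_range Observation-time window (years) for cohort subjects.
#' @return Object of class \code{scenario_config} (a list incl. the derived
#'   \code{ARE2}, \code{omega_sq}, \code{omega0_sq}, \code{zeta},
#'   \code{phi_alpha}).
#' @export
scenario_config <- function(n1 = 1000, k = 4, n2 = 1500, ARE = 1, ARE1 = 1,
                            alpha = 0.25, pi = 0.7,
                            Gamma0 = 20, Gamma01 = Gamma0, Gamma02 = 20,
                            gamma1 = -2, gamma2 = -2, gamma3 = -1.9,
                            delta = 0.3, sigma = 2, sigma0 = 4,
                            nu_sq = 1, tau1_sq = 0.25, tau0_sq = 0.25,
                            obs_range = c(1L, 8L), time_range = c(-1, 3)) {
  if (!(pi > 0 && pi < 1)) stop("pi must be in (0, 1)")
  if (alpha <= 0 || delta <= 0) stop("alpha and delta must be positive")
  if (tau1_sq > nu_sq) stop("tau1_sq cannot exceed nu_sq")
  if (tau0_sq > sigma0^2) stop("tau0_sq cannot exceed sigma0^2")
  if (n1 %/% k < 4) stop("fewer than 4 participants per trial")
  sc <- list(n1 = as.integer(n1), k = as.integer(k), n2 = as.integer(n2),
             ARE = ARE, ARE1 = ARE1, alpha = alpha, pi = pi,
             Gamma0 = Gamma0, Gamma01 = Gamma01, Gamma02 = Gamma02,
             gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
             delta = delta, sigma = sigma, sigma0 = sigma0,
             nu_sq = nu_sq, tau1_sq = tau1_sq, tau0_sq = tau0_sq,
             obs_range = as.integer(obs_range), time_range = time_range)
  sc$ARE2 <- (ARE - pi * ARE1) / (1 - pi)
  sc$omega_sq <- nu_sq - tau1_sq
  sc$omega0_sq <- sigma0^2 - tau0_sq
  sc$zeta <- ARE1 - ARE
  sc$phi_alpha <- (gamma2 - gamma1) * alpha
  structure(sc, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario_config: n1 = %d (k = %d), n2 = %d, alpha = %.2f\n",
    x$n1, x$k, x$n2, x$alpha))
  cat(sprintf("  ARE = %.3g, ARE1 = %.3g, ARE2 = %.3g, pi = %.2f\n",
              x$ARE, x$ARE1, x$ARE2, x$pi))
  cat(sprintf("  biases: phi_alpha = %.3g, zeta = %.3g\n",
              x$phi_alpha, x$zeta))
  invisible(x)
}

#' Projection and generalizability bias of a scenario
#'
#' Projection bias is the error made by extrapolating the pre-offer slope:
#' \code{(gamma2 - gamma1) * alpha}. Generalizability bias is the
#' eligible-stratum effect minus the population effect: \code{ARE1 - ARE}.
#'
#' @param scenario A \code{scenario_config}.
#' @return Named numeric vector \code{c(phi_alpha, zeta)}.
#' @export
biases <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  c(phi_alpha = (scenario$gamma2 - scenario$gamma1) * scenario$alpha,
    zeta = scenario$ARE1 - scenario$ARE)
}

#' Mean potential-outcome trajectories of a simulated individual
#'
#' \code{control_trajectory} is the mean outcome had treatment not been
#' offered: slope \code{gamma1} before t = 0 and \code{gamma2} after.
#' \code{treated_trajectory} adds the treatment-offer difference, which is
#' 0 for t < 0 (treatment cannot precede the offer), reaches exactly
#' \code{Delta} at t = alpha, and is piecewise linear with its only kink at
#' the second change point \code{delta}, beyond which the slope offset is
#' \code{gamma3 - gamma2}. Both functions return deterministic means; the
#' per-observation Normal(0, sigma^2) residual is added by
#' [simulate_trials()] / [simulate_cohort()].
#'
#' @param scenario A \code{scenario_config}.
#' @param gamma0_i Individual outcome at the offer.
#' @param t Numeric vector of times (years).
#' @param Delta Individual treatment effect at alpha.
#' @return Numeric vector of mean outcomes.
#' @export
control_trajectory <- function(scenario, gamma0_i, t) {
  stopifnot(inherits(scenario, "scenario_config"))
  gamma0_i + ifelse(t < 0, scenario$gamma1 * t, scenario$gamma2 * t)
}

#' @rdname control_trajectory
#' @export
treated_trajectory <- function(scenario, gamma0_i, Delta, t) {
  control_trajectory(scenario, gamma0_i, t) +
    treatment_diff(scenario, Delta, t)
}

# Treated-minus-control mean difference at time t (the two alpha/delta
# branches; continuous at delta, equal to Delta at t = alpha, 0 at t <= 0).
treatment_diff <- function(scenario, Delta, t) {
  a <- scenario$alpha; d <- scenario$delta
  g32 <- scenario$gamma3 - scenario$gamma2
  if (a < d) {
    out <- ifelse(t < d, (Delta / a) * t, (Delta / a) * d + g32 * (t - d))
  } else {
    out <- ifelse(t < d, t * (Delta / d + g32 * (1 - a / d)),
                  Delta + g32 * (t - a))
  }
  ifelse(t < 0, 0, out)
}

#' Simulate the k randomized trials of a scenario
#'
#' Draws trial-level effects ARE1j ~ N(ARE1, tau1_sq) and intercept means
#' Gamma01j ~ N(Gamma01, tau0_sq); per participant, an individual effect
#' Delta_i ~ N(ARE1j, omega_sq), an outcome at offer
#' gamma0_i ~ N(Gamma01j, omega0_sq), and a 50:50 randomization arm.
#' Outcomes at t = 0 and t = alpha (with residual noise) give each
#' participant's change score; arms are summarized per trial via
#' [summarize_trial()]. The total trial size n1 is split evenly over the k
#' trials; a non-zero remainder is assigned one extra participant per trial
#' starting from the first, with a message.
#'
#' Uses the current RNG state: seed with \code{set.seed()} or via
#' [simulate_study()] for reproducibility.
#'
#' @param scenario A \code{scenario_config}.
#' @return Data frame of k rows (columns of [summarize_trial()]).
#' @export
simulate_trials <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  base_n <- sc$n1 %/% sc$k
  sizes <- rep(base_n, sc$k)
  rem <- sc$n1 - base_n * sc$k
  if (rem > 0) {
    sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    message("n1 not divisible by k: first ", rem,
            " trial(s) take one extra participant")
  }
  res <- vector("list", sc$k)
  for (j in seq_len(sc$k)) {
    nj <- sizes[j]
    ARE1j <- stats::rnorm(1, sc$ARE1, sqrt(sc$tau1_sq))
    G01j <- stats::rnorm(1, sc$Gamma01, sqrt(sc$tau0_sq))
    Delta <- stats::rnorm(nj, ARE1j, sqrt(sc$omega_sq))
    g0 <- stats::rnorm(nj, G01j, sqrt(sc$omega0_sq))
    R <- stats::rbinom(nj, 1, 0.5)
    y0 <- control_trajectory(sc, g0, rep(0, nj)) +
      stats::rnorm(nj, 0, sc$sigma)
    mu_a <- ifelse(R == 1,
                   treated_trajectory(sc, g0, Delta, rep(sc$alpha, nj)),
                   control_trajectory(sc, g0, rep(sc$alpha, nj)))
    ya <- mu_a + stats::rnorm(nj, 0, sc$sigma)
    change <- ya - y0
    res[[j]] <- summarize_trial(change[R == 1], change[R == 0],
                                trial_id = paste0("trial_", j))
  }
  do.call(rbind, res)
}

#' Simulate the treated cohort of a scenario
#'
#' Draws n2 members of the target population: eligibility Z ~ Bern(pi);
#' individual effect and outcome at offer from the stratum-appropriate
#' marginal distributions (eligible: Delta ~ N(ARE1, nu_sq),
#' gamma0 ~ N(Gamma01, sigma0^2); non-eligible: Delta ~ N(ARE2, nu_sq),
#' gamma0 ~ N(Gamma02, sigma0^2)). Every member is offered treatment;
#' per subject, an observation count uniform on \code{obs_range} and times
#' uniform over \code{time_range} (sorted) give the visit schedule, and
#' outcomes follow the treated trajectory plus Normal(0, sigma^2) residuals.
#' Eligibility flags are set to Z.
#'
#' Uses the current RNG state (see [simulate_study()]).
#'
#' @param scenario A \code{scenario_config}.
#' @return A \code{cohort_dataset} with continuous adjusted scores and
#'   eligibility flags.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  n <- sc$n2
  Z <- stats::rbinom(n, 1, sc$pi)
  Delta <- stats::rnorm(n,
                        ifelse(Z == 1, sc$ARE1, sc$ARE2),
                        sqrt(sc$nu_sq))
  g0 <- stats::rnorm(n,
                     ifelse(Z == 1, sc$Gamma01, sc$Gamma02),
                     sc$sigma0)
  m <- sample(seq(sc$obs_range[1], sc$obs_range[2]), n, replace = TRUE)
  id <- rep(seq_len(n), m)
  tt <- unlist(lapply(m, function(mi)
    sort(stats::runif(mi, sc$time_range[1], sc$time_range[2]))))
  y <- treated_trajectory(sc, g0[id], Delta[id], tt) +
    stats::rnorm(length(tt), 0, sc$sigma)
  ids <- sprintf("s%04d", seq_len(n))
  records <- data.frame(subject_id = ids[id], time_years = tt,
                        numerator = NA_integer_, denominator = NA_integer_,
                        adjusted_score = y)
  baselines <- data.frame(subject_id = ids, eligible_truth = Z == 1)
  cohort_dataset(records, baselines,
                 eligible = stats::setNames(Z == 1, ids))
}

#' Simulate one full study (trials + cohort) reproducibly
#'
#' Seeds the RNG, then draws the trial results and the treated cohort of
#' the scenario. Identical \code{seed} and scenario give bit-identical
#' output.
#'
#' @param scenario A \code{scenario_config}.
#' @param seed Integer seed.
#' @return List with elements \code{trials} (data frame), \code{cohort}
#'   (a \code{cohort_dataset}) and \code{truth} (the scenario).
#' @export
simulate_study <- function(scenario, seed) {
  set.seed(seed)
  trials <- simulate_trials(scenario)
  cohort <- simulate_cohort(scenario)
  list(trials = trials, cohort = cohort, truth = scenario)
}
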