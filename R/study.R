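#' Define a replicated estimator-comparison study
#'
#' @param scenarios A \code{scenario_config} or list of them.
#' @param n_reps Replicates per scenario (default 500).
#' @param estimators Subset of
#'   \code{c("trials_only", "cohort_only", "combined")}.
#' @param master_seed Integer; per-replicate seeds are derived from it
#'   deterministically.
#' @param config An [mcmc_config()] used by the model-based estimators.
#' @param re_spec Random-effects structure passed to the model fits.
#' @return Object of class \code{study_design}.
#' @export
study_design <- function(scenarios, n_reps = 500,
                         estimators = c("trials_only", "cohort_only",
                                        "combined"),
                         master_seed = 1, config = mcmc_config(),
                         re_spec = c("b0", "b1", "b2", "b3")) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  if (!length(scenarios) ||
      !all(vapply(scenarios, inherits, logical(1), "scenario_config")))
    stop("scenarios must be scenario_config objects")
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(n_reps >= 1)
  structure(list(scenarios = scenarios, n_reps = as.integer(n_reps),
                 estimators = estimators,
                 master_seed = as.integer(master_seed),
                 config = config, re_spec = re_spec),
            class = "study_design")
}

# Deterministic per-replicate seed stream (kept below 2^31).
replicate_seed <- function(master_seed, scenario_index, rep_index) {
  (as.integer(master_seed) + 104729L * as.integer(scenario_index) +
     7919L * as.integer(rep_index)) %% 2147483629L
}

#' Run one simulation replicate and compute the competing estimators
#'
#' Generates one study (trials + cohort) from the scenario, then computes
#' the requested estimators: \code{trials_only} pools the per-trial
#' estimates by meta-analysis (point = pooled estimate, SE = pooled SE;
#' no MCMC involved); \code{cohort_only} is the posterior mean (SE =
#' posterior SD) of \code{theta_alpha} from [fit_cohort_model()];
#' \code{combined} is the posterior mean of the mixture effect \code{ARE}
#' from [fit_combined_model()] with the pooled trials converted to the
#' ARE1 prior by [to_prior()].
#'
#' @param scenario A \code{scenario_config}.
#' @param seed Integer seed for this replicate.
#' @param estimators Subset of
#'   \code{c("trials_only", "cohort_only", "combined")}.
#' @param config An [mcmc_config()].
#' @param re_spec Random-effects structure for the model fits.
#' @param pool_method Pooling method for the trials (see [pool()]).
#' @return Data frame with columns \code{estimator}, \code{estimate},
#'   \code{se}, \code{converged} (NA for trials_only).
#' @export
run_replicate <- function(scenario, seed,
                          estimators = c("trials_only", "cohort_only",
                                         "combined"),
                          config = mcmc_config(),
                          re_spec = c("b0", "b1", "b2", "b3"),
                          pool_method = "dersimonian_laird") {
  estimators <- match.arg(estimators, several.ok = TRUE)
  need_trials <- any(c("trials_only", "combined") %in% estimators)
  need_cohort <- any(c("cohort_only", "combined") %in% estimators)
  set.seed(seed)
  trials <- if (need_trials) simulate_trials(scenario) else NULL
  cohort <- if (need_cohort) simulate_cohort(scenario) else NULL
  rows <- list()
  meta <- if (need_trials) pool(trials, method = pool_method) else NULL
  if ("trials_only" %in% estimators)
    rows$trials_only <- data.frame(estimator = "trials_only",
                                   estimate = meta$pooled_estimate,
                                   se = meta$pooled_se, converged = NA)
  if ("cohort_only" %in% estimators) {
    fit <- fit_cohort_model(cohort, alpha = scenario$alpha,
                            re_spec = re_spec, config = config)
    s <- fit$summary[fit$summary$param == "theta_alpha", ]
    rows$cohort_only <- data.frame(estimator = "cohort_only",
                                   estimate = s$mean, se = s$sd,
                                   converged = fit$converged)
  }
  if ("combined" %in% estimators) {
    fit <- fit_combined_model(cohort, alpha = scenario$alpha,
                              prior_ARE1 = to_prior(meta),
                              re_spec = re_spec, config = config)
    s <- fit$summary[fit$summary$param == "ARE", ]
    rows$combined <- data.frame(estimator = "combined",
                                estimate = s$mean, se = s$sd,
                                converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize replicate estimates against the true effect
#'
#' @param estimates Numeric vector of converged replicate estimates
#'   (length >= 2).
#' @param truth True population-average effect.
#' @return One-row data frame: \code{mean_estimate}, \code{absolute_bias}
#'   (|mean - truth|), \code{empirical_se} (sample SD), \code{mse} (mean
#'   squared deviation from truth), \code{n_converged}.
#' @export
summarize_estimates <- function(estimates, truth) {
  if (length(estimates) < 2)
    stop("need at least 2 converged replicates to summarize")
  data.frame(mean_estimate = mean(estimates),
             absolute_bias = abs(mean(estimates) - truth),
             empirical_se = stats::sd(estimates),
             mse = mean((estimates - truth)^2),
             n_converged = length(estimates))
}

#' Run a replicated estimator-comparison study
#'
#' Loops scenarios x replicates with deterministically derived seeds,
#' computes the requested estimators per replicate, drops (but counts)
#' non-converged MCMC replicates, and reports absolute bias, empirical SE
#' and MSE per scenario x estimator, alongside the scenario truth columns.
#'
#' @param design A [study_design()].
#' @param out_csv Optional path: write the report as CSV.
#' @param replicate_log Optional path: write the per-replicate estimates
#'   as CSV.
#' @return Data frame of class \code{comparison_report} with columns
#'   \code{scenario}, \code{estimator}, \code{mean_estimate},
#'   \code{absolute_bias}, \code{empirical_se}, \code{mse},
#'   \code{n_converged}, \code{n_reps}, \code{ARE}, \code{phi_alpha},
#'   \code{zeta}.
#' @export
run_study <- function(design, out_csv = NULL, replicate_log = NULL) {
  stopifnot(inherits(design, "study_design"))
  reps_log <- list()
  report <- list()
  for (si in seq_along(design$scenarios)) {
    sc <- design$scenarios[[si]]
    per_rep <- vector("list", design$n_reps)
    for (ri in seq_len(design$n_reps)) {
      seed <- replicate_seed(design$master_seed, si, ri)
      est <- run_replicate(sc, seed, estimators = design$estimators,
                           config = design$config,
                           re_spec = design$re_spec)
      est$scenario <- si
      est$rep <- ri
      est$seed <- seed
      per_rep[[ri]] <- est
    }
    log_si <- do.call(rbind, per_rep)
    reps_log[[si]] <- log_si
    for (e in design$estimators) {
      d <- log_si[log_si$estimator == e, ]
      keep <- is.na(d$converged) | d$converged
      if (any(!keep))
        message(sum(!keep), " non-converged ", e,
                " replicate(s) excluded in scenario ", si)
      s <- summarize_estimates(d$estimate[keep], sc$ARE)
      s <- cbind(data.frame(scenario = si, estimator = e), s,
                 data.frame(n_reps = design$n_reps, ARE = sc$ARE,
                            phi_alpha = sc$phi_alpha, zeta = sc$zeta))
      report[[length(report) + 1L]] <- s
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  class(report) <- c("comparison_report", class(report))
  if (!is.null(replicate_log))
    utils::write.csv(do.call(rbind, reps_log), replicate_log,
                     row.names = FALSE)
  if (!is.null(out_csv)) utils::write.csv(report, out_csv, row.names = FALSE)
  report
}
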