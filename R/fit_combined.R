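#' Fit the combined trials-plus-cohort Bayesian model
#'
#' Extends the cohort-only change-point model ([fit_cohort_model()]) by
#' stratifying the trajectory on trial eligibility and separating the
#' treatment effect from the projection bias. Each stratum (trial-eligible
#' S = 1, not eligible S = 0) has its own intercept, pre-offer slope, late
#' slope and treatment effect (ARE1, ARE2); a single projection-bias
#' parameter \code{phi_alpha} is shared by both strata, as is the second
#' change point delta, the residual SD and the random effects (including a
#' single subject-level treatment-effect deviation when \code{"b2"} is in
#' \code{re_spec}). The observed eligibility indicators contribute
#' Bernoulli(pi) likelihood terms with pi uniform on (0, 1), and the
#' population-average effect is accumulated per draw as the mixture
#' \code{ARE = pi * ARE1 + (1 - pi) * ARE2} (exact arithmetic on each
#' draw). Meta-analytic evidence from randomized trials enters as the
#' informative normal prior on ARE1; \code{phi_alpha} has a Normal(0,
#' \code{phi_prior_sd}^2) prior and all remaining parameters use the
#' cohort-model priors.
#'
#' @param dataset A \code{cohort_dataset} whose \code{eligible} element
#'   flags every subject; both strata must be non-empty.
#' @param alpha Evaluation time of the treatment effect, in (0, 3].
#' @param prior_ARE1 An \code{informative_prior} (see [to_prior()]), or a
#'   list with positive \code{sd} and \code{mean}.
#' @param re_spec,config,prior_sd_coef,delta_range As in
#'   [fit_cohort_model()].
#' @param phi_prior_sd SD of the zero-mean normal prior on the projection
#'   bias (default 100).
#' @param phi_fixed Optional numeric: fix the projection bias at this value
#'   instead of sampling it (mainly for model checking; with
#'   \code{phi_fixed = 0} and every subject eligible the model reduces to
#'   the cohort-only model with ARE1 in place of theta_alpha). When the
#'   projection bias is fixed, an empty stratum is permitted.
#' @return Object of class \code{c("combined_fit", "posterior_summary")}
#'   including parameters \code{ARE}, \code{ARE1}, \code{ARE2},
#'   \code{phi_alpha}, \code{pi}, the stratum trajectory coefficients,
#'   \code{delta} and \code{sigma}.
#' @export
fit_combined_model <- function(dataset, alpha, prior_ARE1,
                               re_spec = c("b0", "b1", "b2", "b3"),
                               config = mcmc_config(),
                               prior_sd_coef = 100,
                               phi_prior_sd = 100,
                               delta_range = c(0, 3),
                               phi_fixed = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!(alpha > 0 && alpha <= 3)) stop("alpha must be in (0, 3]")
  if (is.null(prior_ARE1$sd) || !is.finite(prior_ARE1$sd) ||
      prior_ARE1$sd <= 0)
    stop("prior_ARE1 must have a finite positive sd")
  if (is.null(dataset$eligible))
    stop("dataset must carry eligibility flags (see flag_eligibility)")
  r <- dataset$records
  ids <- unique(r$subject_id)
  elig <- dataset$eligible[as.character(ids)]
  if (anyNA(elig))
    stop("missing eligibility flag for subject(s): ",
         paste(utils::head(ids[is.na(elig)], 5), collapse = ", "))
  if ((all(elig) || !any(elig)) && is.null(phi_fixed))
    stop("both eligibility strata must be non-empty ",
         "(ARE2 or phi_alpha would be unidentified)")
  subj <- match(r$subject_id, ids)
  if (!any(r$time_years > 0))
    stop("treatment effect unidentifiable: no post-offer observations")
  built <- build_combined_model(re_spec, prior_mean = prior_ARE1$mean,
                                prior_sd = prior_ARE1$sd,
                                prior_sd_coef = prior_sd_coef,
                                phi_prior_sd = phi_prior_sd,
                                delta_range = delta_range,
                                phi_fixed = phi_fixed)
  dat <- c(list(y = r$adjusted_score, t = r$time_years, subj = subj,
                N = nrow(r), n = length(ids), alpha = alpha,
                S = as.integer(elig), g = 2L - as.integer(elig),
                pre = r$time_years * (r$time_years < 0),
                pos = as.numeric(r$time_years > 0)),
           built$data_extra)
  draws <- run_jags(built$model, dat, built$monitors, config,
                    inits_extra = list(delta = mean(delta_range),
                                       sigma = max(stats::sd(dat$y), 0.1)))
  fit <- posterior_summary(draws, rename = built$rename,
                           extra = list(alpha = alpha, re_spec = re_spec,
                                        config = config,
                                        prior_ARE1 = prior_ARE1))
  class(fit) <- c("combined_fit", class(fit))
  fit$converged <- if (config$chains >= 2)
    check_convergence(fit, config$rhat_max) else NA
  fit
}

#' Population-average treatment effect as an eligibility mixture
#'
#' Combines draws (or scalars) of the stratum treatment effects into the
#' population-average effect, elementwise:
#' \code{pi * ARE1 + (1 - pi) * ARE2}.
#'
#' @param ARE1,ARE2,pi Equal-length numeric vectors (posterior draws) or
#'   scalars.
#' @return Numeric vector of population-average effects.
#' @export
mixture_effect <- function(ARE1, ARE2, pi) {
  n <- unique(c(length(ARE1), length(ARE2), length(pi)))
  n <- n[n != 1L]
  if (length(n) > 1)
    stop("ARE1, ARE2 and pi must have equal length (or be scalars)")
  pi * ARE1 + (1 - pi) * ARE2
}
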