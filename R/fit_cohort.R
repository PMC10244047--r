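#' Fit the cohort-only Bayesian piecewise change-point model
#'
#' Models the outcome trajectories of a cohort who were all offered
#' treatment: a subject-level piecewise linear curve with a change point at
#' the offer (t = 0) and a second, estimated change point delta, written so
#' that the treatment effect at evaluation time \code{alpha} --- the gap
#' between the treated trajectory and the continuation of the pre-offer
#' line --- appears directly as the parameter \code{theta_alpha}. Under the
#' assumption that untreated patients would have continued their pre-offer
#' trajectory, \code{theta_alpha} estimates the average effect of the
#' treatment offer; any projection bias in that assumption is absorbed into
#' \code{theta_alpha} (see [fit_combined_model()] for the bias-corrected
#' variant).
#'
#' Priors: coefficients Normal(0, \code{prior_sd_coef}^2); residual SD
#' uniform on (0, 100); delta uniform on \code{delta_range}; random-effect
#' scales per the hierarchy described in [mcmc_config()]'s model notes ---
#' a U(0, 100) SD for a single effect, U(0, 100) SDs with a U(-1, 1)
#' correlation for two, and a scaled inverse-Wishart with U(0, 100) scale
#' parameters for three or more. Because delta is a parameter, the basis
#' indicator terms are recomputed at every draw inside the sampler.
#'
#' @param dataset A \code{cohort_dataset}; at least one subject must have
#'   observations both before and after the offer.
#' @param alpha Evaluation time of the treatment effect, in (0, 3].
#' @param re_spec Character subset of \code{c("b0","b1","b2","b3")} naming
#'   the random effects: intercept, pre-offer slope, treatment effect and
#'   late slope. Default all four.
#' @param config An [mcmc_config()].
#' @param prior_sd_coef SD of the vague normal priors on the fixed
#'   coefficients (score units; default 100).
#' @param delta_range Support of the uniform prior on the second change
#'   point (years); default \code{c(0, 3)}.
#' @return Object of class \code{c("cohort_fit", "posterior_summary")} with
#'   posterior mean/SD/interval, split-R-hat and effective sample size per
#'   parameter, and the pooled draws. The point estimate of the treatment
#'   effect is the posterior mean of \code{theta_alpha}; its reported SE is
#'   the posterior SD.
#' @export
fit_cohort_model <- function(dataset, alpha,
                             re_spec = c("b0", "b1", "b2", "b3"),
                             config = mcmc_config(),
                             prior_sd_coef = 100,
                             delta_range = c(0, 3)) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!(alpha > 0 && alpha <= 3)) stop("alpha must be in (0, 3]")
  r <- dataset$records
  ids <- unique(r$subject_id)
  subj <- match(r$subject_id, ids)
  if (!any(r$time_years > 0))
    stop("treatment effect unidentifiable: no post-offer observations")
  has_pre <- tapply(r$time_years < 0, subj, any)
  has_post <- tapply(r$time_years > 0, subj, any)
  if (!any(has_pre & has_post))
    stop("need at least one subject observed both before and after offer")
  built <- build_cohort_model(re_spec, prior_sd_coef, delta_range)
  dat <- c(list(y = r$adjusted_score, t = r$time_years, subj = subj,
                N = nrow(r), n = length(ids), alpha = alpha,
                pre = r$time_years * (r$time_years < 0),
                pos = as.numeric(r$time_years > 0)),
           built$data_extra)
  # start sigma at the marginal outcome SD so the first sweeps see a smooth
  # likelihood in delta before the residual scale tightens
  draws <- run_jags(built$model, dat, built$monitors, config,
                    inits_extra = list(delta = mean(delta_range),
                                       sigma = max(stats::sd(dat$y), 0.1)))
  fit <- posterior_summary(draws, rename = built$rename,
                           extra = list(alpha = alpha, re_spec = re_spec,
                                        config = config))
  class(fit) <- c("cohort_fit", class(fit))
  fit$converged <- if (config$chains >= 2)
    check_convergence(fit, config$rhat_max) else NA
  fit
}
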