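#' Summarize one trial's change scores into an effect estimate
#'
#' Computes the treated-minus-control difference in mean change score from
#' treatment offer to the evaluation time, with standard error
#' \eqn{\sqrt{s_t^2/n_t + s_c^2/n_c}} from the sample variances.
#'
#' @param treated_changes,control_changes Numeric vectors of per-participant
#'   change scores (outcome at the evaluation time minus outcome at offer);
#'   each arm needs at least 2 observations.
#' @param trial_id Identifier stored with the result.
#' @return One-row data frame with columns \code{trial_id}, \code{estimate},
#'   \code{se}, \code{n_treated}, \code{n_control} and logical
#'   \code{degenerate} (TRUE when both arms have zero variance, so the SE
#'   is 0 and the trial cannot enter an inverse-variance pool).
#' @export
summarize_trial <- function(treated_changes, control_changes,
                            trial_id = NA_character_) {
  nt <- length(treated_changes); nc <- length(control_changes)
  if (nt < 2 || nc < 2)
    stop("each arm needs at least 2 observations (sample variance undefined)")
  est <- mean(treated_changes) - mean(control_changes)
  se <- sqrt(stats::var(treated_changes) / nt +
             stats::var(control_changes) / nc)
  data.frame(trial_id = trial_id, estimate = est, se = se,
             n_treated = nt, n_control = nc, degenerate = se == 0)
}

#' Pool per-trial effect estimates by meta-analysis
#'
#' Inverse-variance pooling of per-trial effect estimates, either under a
#' common-effect (fixed-effect) model or DerSimonian-Laird random effects
#' (between-trial variance by the moment estimator, truncated at zero).
#' Delegates to \code{metafor::rma}.
#'
#' @param trials Data frame with columns \code{estimate} and \code{se}
#'   (e.g. rows from [summarize_trial()] or [read_trials_csv()]).
#' @param method \code{"dersimonian_laird"} (default) or
#'   \code{"fixed_effect"}.
#' @return Object of class \code{meta_result}: list with
#'   \code{pooled_estimate}, \code{pooled_se}, \code{tau_sq}, \code{k},
#'   \code{method}.
#' @export
pool <- function(trials, method = c("dersimonian_laird", "fixed_effect")) {
  method <- match.arg(method)
  trials <- as.data.frame(trials)
  if (!all(c("estimate", "se") %in% names(trials)))
    stop("trials must have columns estimate and se")
  k <- nrow(trials)
  if (k == 0L) stop("no trials to pool")
  if (any(!is.finite(trials$se) | trials$se <= 0))
    stop("all trial standard errors must be positive")
  fit <- metafor::rma(yi = trials$estimate, sei = trials$se,
                      method = if (method == "fixed_effect") "FE" else "DL")
  structure(list(pooled_estimate = as.numeric(fit$beta),
                 pooled_se = as.numeric(fit$se),
                 tau_sq = if (method == "fixed_effect") 0 else fit$tau2,
                 k = k, method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, k = %d): %.4f (SE %.4f), tau^2 = %.4f\n",
              x$method, x$k, x$pooled_estimate, x$pooled_se, x$tau_sq))
  invisible(x)
}

#' Convert a pooled meta-analysis result to an informative normal prior
#'
#' The prior for the trial-eligible treatment effect ARE1 is normal with
#' mean the pooled effect estimate and standard deviation the pooled
#' standard error.
#'
#' @param meta A \code{meta_result} from [pool()], or a list/data frame with
#'   \code{pooled_estimate} and \code{pooled_se}.
#' @return Object of class \code{informative_prior}: list with \code{mean},
#'   \code{sd}, \code{family = "normal"}.
#' @examples
#' to_prior(list(pooled_estimate = 1.10, pooled_se = 0.316))
#' @export
to_prior <- function(meta) {
  m <- meta$pooled_estimate; s <- meta$pooled_se
  if (!is.finite(s) || s <= 0) stop("pooled_se must be finite and positive")
  structure(list(mean = as.numeric(m), sd = as.numeric(s),
                 family = "normal"),
            class = "informative_prior")
}

#' @export
print.informative_prior <- function(x, ...) {
  cat(sprintf("informative_prior: Normal(mean = %.4f, sd = %.4f)\n",
              x$mean, x$sd))
  invisible(x)
}

#' Read / write trial evidence as CSV
#'
#' Two layouts are accepted: aggregated, with columns \code{trial_id},
#' \code{estimate}, \code{se}; or per-arm summaries with columns
#' \code{trial_id}, \code{n_t}, \code{mean_change_t}, \code{sd_t},
#' \code{n_c}, \code{mean_change_c}, \code{sd_c}, which are reduced to
#' estimate and SE on read.
#'
#' @param path CSV file path.
#' @return \code{read_trials_csv} returns a data frame with columns
#'   \code{trial_id}, \code{estimate}, \code{se} (plus arm sizes when
#'   available); \code{write_trials_csv} returns its input invisibly.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("estimate", "se") %in% names(d))) {
    return(d)
  }
  arm_cols <- c("n_t", "mean_change_t", "sd_t", "n_c", "mean_change_c", "sd_c")
  if (all(arm_cols %in% names(d))) {
    out <- data.frame(
      trial_id = d$trial_id,
      estimate = d$mean_change_t - d$mean_change_c,
      se = sqrt(d$sd_t^2 / d$n_t + d$sd_c^2 / d$n_c),
      n_treated = d$n_t, n_control = d$n_c)
    return(out)
  }
  stop("trials CSV needs either (estimate, se) or per-arm summary columns")
}

#' @rdname read_trials_csv
#' @param trials Data frame of aggregated trial results.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(trials)
}
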