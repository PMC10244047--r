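#' Trajectory parameters for the piecewise linear change-point model
#'
#' The mean outcome trajectory of a treated subject is piecewise linear
#' with change points at the treatment offer (t = 0) and at a later time
#' delta: slope \code{beta1} before the offer, an initial post-offer slope
#' (reparametrized out in favour of the treatment effect
#' \code{theta_alpha}), and slope \code{beta3} after delta. The treatment
#' effect at evaluation time alpha is the gap at t = alpha between the
#' treated trajectory and the continuation of the pre-offer line.
#'
#' @param beta0 Intercept at t = 0 (score units).
#' @param beta1 Pre-offer slope (score/yr).
#' @param beta3 Slope after the second change point (score/yr).
#' @param delta Second change-point time in years, in (0, 3).
#' @param theta_alpha Treatment-effect parameter at t = alpha (score units).
#' @param sigma Residual SD (score units), optional.
#' @return Object of class \code{trajectory_params}.
#' @export
trajectory_params <- function(beta0, beta1, beta3, delta, theta_alpha,
                              sigma = NULL) {
  if (!is.numeric(delta) || delta <= 0)
    stop("delta must be positive")
  if (!is.null(sigma) && sigma < 0) stop("sigma must be non-negative")
  structure(list(beta0 = beta0, beta1 = beta1, beta3 = beta3, delta = delta,
                 theta_alpha = theta_alpha, sigma = sigma),
            class = "trajectory_params")
}

#' Treatment effect implied by the piecewise slopes
#'
#' Given the pre-offer slope, the initial post-offer slope, the late slope
#' and the second change point, returns the gap at t = alpha between the
#' treated trajectory and the extension of the pre-offer line:
#' \deqn{\theta_\alpha = (\beta_2-\beta_1)\alpha} when \eqn{\alpha < \delta},
#' and \eqn{(\beta_2-\beta_3)\delta + (\beta_3-\beta_1)\alpha} otherwise.
#'
#' @param beta1,beta2,beta3 Slopes (score/yr): pre-offer, initial
#'   post-offer, after the second change point.
#' @param delta Second change-point time (> 0).
#' @param alpha Evaluation time (> 0).
#' @return The treatment effect at alpha (score units). Vectorized.
#' @export
theta_from_betas <- function(beta1, beta2, beta3, delta, alpha) {
  stopifnot(all(alpha > 0), all(delta > 0))
  ifelse(alpha < delta,
         (beta2 - beta1) * alpha,
         (beta2 - beta3) * delta + (beta3 - beta1) * alpha)
}

#' Initial post-offer slope implied by the treatment effect
#'
#' Inverts [theta_from_betas()]: recovers beta2 from the treatment effect
#' and the other parameters.
#'
#' @inheritParams theta_from_betas
#' @param theta_alpha Treatment effect at alpha.
#' @return The initial post-offer slope beta2. Vectorized.
#' @export
beta2_from_theta <- function(theta_alpha, beta1, beta3, delta, alpha) {
  stopifnot(all(alpha > 0), all(delta > 0))
  ifelse(alpha < delta,
         theta_alpha / alpha + beta1,
         (theta_alpha - (beta3 - beta1) * alpha) / delta + beta3)
}

# Basis functions of the reparametrized treated-trajectory mean: the mean is
# beta0 + beta1*B1 + theta_alpha*B2 + beta3*B3. Shared between the R-side
# evaluator and the JAGS model builders (which re-express them per draw
# because delta is a parameter).
trajectory_basis <- function(t, delta, alpha) {
  a_lt_d <- alpha < delta
  c1 <- ifelse(a_lt_d, 1, alpha / delta)
  c2 <- ifelse(a_lt_d, 1 / alpha, 1 / delta)
  b3m <- ifelse(a_lt_d, 0, 1 - alpha / delta)
  pos <- as.numeric(t > 0)
  mnt <- pmin(t, delta) * pos
  list(B1 = t * (t < 0) + c1 * mnt,
       B2 = c2 * mnt,
       B3 = b3m * mnt + (t - delta) * (t >= delta))
}

#' Mean treated trajectory under the reparametrized model
#'
#' Evaluates the mean outcome of a treated subject at time \code{t} using
#' the indicator-basis form in which the initial post-offer slope is
#' replaced by the treatment effect \code{theta_alpha}. The curve is
#' piecewise linear and continuous in \code{t}, with kinks only at 0 and
#' \code{delta}; at \code{t = 0} it equals \code{beta0}, and when
#' \code{theta_alpha = 0} and \code{beta3 = beta1} it reduces to the
#' untreated line \code{beta0 + beta1 t}.
#'
#' @param t Numeric vector of times (years relative to offer).
#' @param params A [trajectory_params()] object.
#' @param alpha Evaluation time of the treatment effect (> 0).
#' @return Numeric vector of mean outcomes.
#' @export
mean_trajectory <- function(t, params, alpha) {
  stopifnot(inherits(params, "trajectory_params"), alpha > 0)
  if (params$delta <= 0) stop("delta must be positive")
  B <- trajectory_basis(t, params$delta, alpha)
  params$beta0 + params$beta1 * B$B1 + params$theta_alpha * B$B2 +
    params$beta3 * B$B3
}
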