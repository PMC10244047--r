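#' MCMC sampler settings
#'
#' Settings for the JAGS-based model fits. Per chain, \code{iter} total
#' iterations are run of which the first \code{warmup} (default half) are
#' discarded; half of the warmup is used for JAGS adaptation. Per-chain
#' random number generators are seeded deterministically from \code{seed}.
#'
#' @param chains Number of chains (default 4; convergence checks need >= 2).
#' @param iter Total iterations per chain including warmup.
#' @param warmup Warmup iterations per chain (default \code{iter / 2}).
#' @param seed Integer seed.
#' @param rhat_max Split-R-hat threshold used by [check_convergence()].
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return List of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 4, iter = 2000, warmup = NULL, seed = 1,
                        rhat_max = 1.05, quiet = TRUE) {
  if (is.null(warmup)) warmup <- floor(iter / 2)
  stopifnot(chains >= 1, iter > warmup, warmup >= 2)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 rhat_max = rhat_max, quiet = isTRUE(quiet)),
            class = "mcmc_config")
}

# Split-R-hat: each chain is split in half and the potential scale reduction
# factor computed over the 2*chains half-chains (rank-free version).
split_rhat_vec <- function(chains_list) {
  halves <- list()
  for (ch in chains_list) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Run a JAGS model string and return a coda::mcmc.list plus a summary table.
run_jags <- function(model_string, data, monitors, config, inits_extra = list()) {
  rjags::load.module("glm", quiet = TRUE)
  n_adapt <- max(2L, floor(config$warmup / 2))
  n_burn <- config$warmup - n_adapt
  inits <- lapply(seq_len(config$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (config$seed + 1117L * ch) %% 2147483647L),
      inits_extra)
  })
  # "Adaptation incomplete" only notes that JAGS would keep tuning its
  # samplers with a longer adaptation phase; with deliberately short warmups
  # it is expected, so it is muffled rather than surfaced per fit.
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_string), data = data,
                      n.chains = config$chains, n.adapt = n_adapt,
                      inits = inits, quiet = config$quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (n_burn > 0)
    stats::update(jm, n_burn,
                  progress.bar = if (config$quiet) "none" else "text")
  rjags::coda.samples(jm, monitors, n.iter = config$iter - config$warmup,
                      progress.bar = if (config$quiet) "none" else "text")
}

# Build a posterior_summary object from an mcmc.list.
posterior_summary <- function(draws, rename = NULL, extra = list()) {
  mats <- lapply(draws, as.matrix)
  pars <- colnames(mats[[1]])
  all_draws <- do.call(rbind, mats)
  smry <- data.frame(
    param = pars,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    lower_95 = apply(all_draws, 2, stats::quantile, 0.025),
    upper_95 = apply(all_draws, 2, stats::quantile, 0.975),
    row.names = NULL)
  smry$rhat <- vapply(pars, function(p)
    split_rhat_vec(lapply(mats, function(m) m[, p])), numeric(1))
  smry$ess <- vapply(pars, function(p)
    sum(vapply(mats, function(m) coda::effectiveSize(m[, p]), numeric(1))),
    numeric(1))
  if (!is.null(rename)) {
    idx <- match(smry$param, names(rename))
    smry$param[!is.na(idx)] <- unname(rename[idx[!is.na(idx)]])
    for (m in seq_along(mats)) {
      cn <- colnames(mats[[m]])
      i2 <- match(cn, names(rename))
      colnames(mats[[m]])[!is.na(i2)] <- unname(rename[i2[!is.na(i2)]])
    }
    draws <- coda::as.mcmc.list(lapply(mats, coda::mcmc))
  }
  structure(c(list(summary = smry, draws = draws,
                   diagnostics = list(max_rhat = max(smry$rhat),
                                      min_ess = min(smry$ess),
                                      n_divergent = 0L,
                                      n_chains = length(mats))),
              extra),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat("posterior_summary (", x$diagnostics$n_chains, " chains, max R-hat ",
      sprintf("%.3f", x$diagnostics$max_rhat), ")\n", sep = "")
  print(cbind(x$summary["param"],
              round(x$summary[setdiff(names(x$summary), "param")], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Extract posterior draws of one or more parameters
#'
#' @param fit A \code{posterior_summary}.
#' @param pars Character vector of parameter names.
#' @return Matrix of pooled posterior draws (rows = draws).
#' @export
posterior_draws <- function(fit, pars) {
  stopifnot(inherits(fit, "posterior_summary"))
  m <- do.call(rbind, lapply(fit$draws, as.matrix))
  missing <- setdiff(pars, colnames(m))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  m[, pars, drop = FALSE]
}

#' Check MCMC convergence of a fitted model
#'
#' Declares convergence when every parameter's split-R-hat is at or below
#' the threshold. (The Gibbs sampler has no notion of divergent
#' transitions, so the stored divergence count is always zero.)
#'
#' @param fit A \code{posterior_summary} with at least 2 chains.
#' @param rhat_max Threshold, default 1.05.
#' @return Logical.
#' @export
check_convergence <- function(fit, rhat_max = 1.05) {
  stopifnot(inherits(fit, "posterior_summary"))
  if (fit$diagnostics$n_chains < 2)
    stop("convergence check requires at least 2 chains")
  fit$diagnostics$max_rhat <= rhat_max && fit$diagnostics$n_divergent == 0
}
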