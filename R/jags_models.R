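# JAGS model-code builders for the piecewise change-point models.
#
# The second change point delta is a model parameter, so every basis term
# involving delta (min(t, delta), the alpha<delta indicator, the slope
# weights) is re-expressed inside the model and recomputed at each draw;
# only the delta-free pieces (t*1{t<0}, 1{t>0}) are precomputed as data.
#
# Random-effects prior recipes, by number of effects:
#   1:  half-bounded SD, sd ~ U(0, 100)
#   2:  bivariate normal via its Cholesky factor (exact reparametrization),
#       SDs ~ U(0, 100), correlation ~ U(-1, 1)
#   >=3: scaled inverse-Wishart: b_k = xi_k * eta_k with
#       eta ~ MVN(0, Q^-1), Q ~ Wishart(I, d+1), scale xi_k ~ U(0, 100)

RE_NAMES <- c("b0", "b1", "b2", "b3")

# Returns list(code = prior block, use = named chr of per-subject terms,
# monitors, data_extra, rename)
build_re_block <- function(re_spec) {
  re_spec <- match.arg(re_spec, RE_NAMES, several.ok = TRUE)
  d <- length(re_spec)
  arr <- paste0("re", re_spec)              # e.g. reb0[i]
  use <- stats::setNames(rep("0", 4), RE_NAMES)
  use[re_spec] <- paste0(arr, "[subj[j]]")
  sds <- paste0("sd_", re_spec)
  if (d == 1) {
    code <- paste0(
      "  for (i in 1:n) { ", arr, "[i] ~ dnorm(0, 1 / (", sds,
      " * ", sds, ")) }\n",
      "  ", sds, " ~ dunif(0, 100)\n")
    return(list(code = code, use = use, monitors = sds,
                data_extra = list(), rename = NULL))
  }
  if (d == 2) {
    code <- paste0(
      "  for (i in 1:n) {\n",
      "    zre[i,1] ~ dnorm(0, 1)\n    zre[i,2] ~ dnorm(0, 1)\n",
      "    ", arr[1], "[i] <- ", sds[1], " * zre[i,1]\n",
      "    ", arr[2], "[i] <- ", sds[2],
      " * (rho_re * zre[i,1] + sqrt(1 - rho_re^2) * zre[i,2])\n",
      "  }\n",
      "  ", sds[1], " ~ dunif(0, 100)\n",
      "  ", sds[2], " ~ dunif(0, 100)\n",
      "  rho_re ~ dunif(-1, 1)\n")
    return(list(code = code, use = use, monitors = c(sds, "rho_re"),
                data_extra = list(), rename = NULL))
  }
  assign_lines <- paste0("    ", arr, "[i] <- xi[", seq_len(d),
                         "] * eta[i,", seq_len(d), "]", collapse = "\n")
  sd_lines <- paste0("  ", sds, " <- xi[", seq_len(d), "] * sqrt(SigEta[",
                     seq_len(d), ",", seq_len(d), "])", collapse = "\n")
  code <- paste0(
    "  for (i in 1:n) {\n",
    "    eta[i,1:", d, "] ~ dmnorm(zerosRE[1:", d, "], Qre[1:", d,
    ",1:", d, "])\n",
    assign_lines, "\n  }\n",
    "  Qre[1:", d, ",1:", d, "] ~ dwish(Ire[1:", d, ",1:", d, "], ",
    d + 1, ")\n",
    "  for (kre in 1:", d, ") { xi[kre] ~ dunif(0, 100) }\n",
    "  SigEta[1:", d, ",1:", d, "] <- inverse(Qre[1:", d, ",1:", d, "])\n",
    sd_lines, "\n")
  list(code = code, use = use, monitors = sds,
       data_extra = list(zerosRE = rep(0, d), Ire = diag(d)),
       rename = NULL)
}

# Shared likelihood-basis block; `coef` is a named chr vector giving the
# JAGS expressions for the four coefficients (intercept, pre-slope,
# treatment, late slope) at observation j.
build_likelihood <- function(coef, re_use) {
  paste0(
    "  for (j in 1:N) {\n",
    "    mnt[j] <- min(t[j], delta) * pos[j]\n",
    "    mu[j] <- ", coef[["b0"]], " + ", re_use[["b0"]], "\n",
    "      + (", coef[["b1"]], " + ", re_use[["b1"]],
    ") * (pre[j] + c1 * mnt[j])\n",
    "      + (", coef[["b2"]], " + ", re_use[["b2"]], ") * c2 * mnt[j]\n",
    "      + (", coef[["b3"]], " + ", re_use[["b3"]],
    ") * (b3m * mnt[j] + (t[j] - delta) * step(t[j] - delta))\n",
    "    y[j] ~ dnorm(mu[j], tauy)\n",
    "  }\n",
    "  altd <- step(delta - alpha)\n",
    "  c1 <- altd + (alpha / delta) * (1 - altd)\n",
    "  c2 <- altd / alpha + (1 - altd) / delta\n",
    "  b3m <- (1 - alpha / delta) * (1 - altd)\n")
}

build_cohort_model <- function(re_spec, prior_sd_coef = 100,
                               delta_range = c(0, 3), sigma_max = 100) {
  re <- build_re_block(re_spec)
  coef_prec <- 1 / prior_sd_coef^2
  lik <- build_likelihood(
    coef = c(b0 = "beta0", b1 = "beta1", b2 = "theta", b3 = "beta3"),
    re_use = re$use)
  model <- paste0(
    "model {\n", lik, re$code,
    "  beta0 ~ dnorm(0, ", coef_prec, ")\n",
    "  beta1 ~ dnorm(0, ", coef_prec, ")\n",
    "  theta ~ dnorm(0, ", coef_prec, ")\n",
    "  beta3 ~ dnorm(0, ", coef_prec, ")\n",
    "  sigma ~ dunif(0, ", sigma_max, ")\n",
    "  tauy <- 1 / (sigma * sigma)\n",
    "  delta ~ dunif(", delta_range[1], ", ", delta_range[2], ")\n",
    "}\n")
  list(model = model,
       monitors = c("beta0", "beta1", "theta", "beta3", "delta", "sigma",
                    re$monitors),
       data_extra = re$data_extra,
       rename = c(theta = "theta_alpha"))
}

build_combined_model <- function(re_spec, prior_mean, prior_sd,
                                 prior_sd_coef = 100, phi_prior_sd = 100,
                                 delta_range = c(0, 3), sigma_max = 100,
                                 phi_fixed = NULL) {
  re <- build_re_block(re_spec)
  coef_prec <- 1 / prior_sd_coef^2
  lik <- build_likelihood(
    coef = c(b0 = "beta0s[g[subj[j]]]", b1 = "beta1s[g[subj[j]]]",
             b2 = "AREs[g[subj[j]]] + phi", b3 = "beta3s[g[subj[j]]]"),
    re_use = re$use)
  model <- paste0(
    "model {\n", lik, re$code,
    "  for (i in 1:n) { S[i] ~ dbern(pi) }\n",
    "  pi ~ dunif(0, 1)\n",
    "  AREs[1] ~ dnorm(", prior_mean, ", ", 1 / prior_sd^2, ")\n",
    "  AREs[2] ~ dnorm(0, ", coef_prec, ")\n",
    if (is.null(phi_fixed))
      paste0("  phi ~ dnorm(0, ", 1 / phi_prior_sd^2, ")\n")
    else paste0("  phi <- ", phi_fixed, "\n"),
    "  ARE <- pi * AREs[1] + (1 - pi) * AREs[2]\n",
    "  for (gs in 1:2) {\n",
    "    beta0s[gs] ~ dnorm(0, ", coef_prec, ")\n",
    "    beta1s[gs] ~ dnorm(0, ", coef_prec, ")\n",
    "    beta3s[gs] ~ dnorm(0, ", coef_prec, ")\n",
    "  }\n",
    "  sigma ~ dunif(0, ", sigma_max, ")\n",
    "  tauy <- 1 / (sigma * sigma)\n",
    "  delta ~ dunif(", delta_range[1], ", ", delta_range[2], ")\n",
    "}\n")
  list(model = model,
       monitors = c("ARE", "AREs", "phi", "pi", "beta0s", "beta1s",
                    "beta3s", "delta", "sigma", re$monitors),
       data_extra = re$data_extra,
       rename = c("AREs[1]" = "ARE1", "AREs[2]" = "ARE2",
                  phi = "phi_alpha",
                  "beta0s[1]" = "beta01", "beta0s[2]" = "beta02",
                  "beta1s[1]" = "beta11", "beta1s[2]" = "beta12",
                  "beta3s[1]" = "beta31", "beta3s[2]" = "beta32"))
}
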