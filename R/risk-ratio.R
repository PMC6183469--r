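#' The mimicry kill-risk ratio
#'
#' A harmless snake encountered by a human runs a baseline risk `mu0` (the
#' probability the human would kill any snake) plus an extra risk
#' `muv * eps_i`: the probability the human kills only venomous adders,
#' times the probability they mistake species `i` for an adder. The
#' fold-increase in kill risk attributable to viper resemblance is the
#' ratio of total to baseline risk:
#' \deqn{\phi_i = \frac{\mu_0 + \mu_v\,\varepsilon_i}{\mu_0}
#'             = 1 + \frac{\mu_v\,\varepsilon_i}{\mu_0}.}
#' With all inputs in \[0, 1\] and `mu0 > 0`, `phi >= 1`, with equality
#' exactly when `muv * eps_i = 0`.
#'
#' @param mu0 baseline kill probability, must be > 0.
#' @param muv selective (vipers-only) kill probability.
#' @param eps_i probability species i is identified as an adder by a
#'   selective killer.
#' @return the risk ratio, a plain number (exact arithmetic, no randomness).
#' @examples
#' risk_ratio(0.098, 0.206, 0.677)
#' @export
risk_ratio <- function(mu0, muv, eps_i) {
  if (any(c(mu0, muv, eps_i) < 0) || any(c(mu0, muv, eps_i) > 1)) {
    mr_error("mu0, muv and eps_i must be probabilities in [0, 1]",
             "mimicryrisk_domain_error")
  }
  if (mu0 == 0) {
    mr_error(paste("mu0 = 0: the risk ratio is undefined at zero baseline",
                   "kill probability (no respondent willing to kill",
                   "indiscriminately); phi has no finite value"),
             "mimicryrisk_domain_error")
  }
  1 + (muv * eps_i) / mu0
}

#' Bundle the inputs of the risk-ratio calculation
#'
#' @param mu0,muv [fit_intercept_glm()] results for the kill-all and
#'   kill-selective proportions (they must come from the same respondent
#'   total `n`).
#' @param eps named list, one entry per species, each a list with
#'   logit-scale `eta` and `se_eta` for the probability that species is
#'   identified as an adder by a selective killer (typically
#'   [population_probability()] on the selective-subset GLMM).
#' @return list of class `kill_risk_inputs`.
#' @export
kill_risk_inputs <- function(mu0, muv, eps) {
  stopifnot(inherits(mu0, "proportion_estimate"),
            inherits(muv, "proportion_estimate"))
  if (mu0$n != muv$n) {
    mr_error("mu0 and muv must derive from the same respondent total n",
             "mimicryrisk_schema_error")
  }
  for (sp in names(eps)) {
    if (!all(c("eta", "se_eta") %in% names(eps[[sp]]))) {
      mr_error(sprintf("eps entry '%s' must have components eta and se_eta", sp),
               "mimicryrisk_schema_error")
    }
  }
  structure(list(mu0 = mu0, muv = muv, eps = eps),
            class = "kill_risk_inputs")
}

resolve_boundary <- function(est, what, continuity_correction) {
  if (!is.finite(est$eta_hat) || !is.finite(est$se_eta)) {
    if (continuity_correction) return(continuity_correct(est))
    mr_error(sprintf(
      paste("%s is at the boundary (k = 0 or k = n): its logit-scale",
            "standard error is infinite. Re-run with",
            "continuity_correction = TRUE to add 1/2 to successes and",
            "failures."), what),
      "mimicryrisk_boundary_error")
  }
  est
}

#' Monte Carlo distribution of the kill-risk ratio
#'
#' Propagates the uncertainty of `mu0`, `muv` and `eps_i` through the risk
#' ratio by simulation: each draw samples the three parameters
#' independently from normal distributions on the logit (link) scale
#' centred at their estimates, back-transforms each to a probability, and
#' applies [risk_ratio()]. The reported interval is the 2.5/97.5 percentile
#' range of the draws. Deterministic given `seed`.
#'
#' Options depart from the default interpretation for sensitivity checks:
#' `scale = "response"` samples truncated normals on the probability scale
#' (delta-method SE) instead of the link scale, and `joint_attitude = TRUE`
#' resamples the (kill-all, kill-selective) counts jointly from a
#' multinomial, respecting their negative correlation in the shared sample.
#'
#' @param inputs a [kill_risk_inputs()].
#' @param species which species' eps entry to use (e.g. `"smooth"`).
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed; default 20140601 (documented package default).
#' @param scale `"link"` (default) or `"response"`.
#' @param joint_attitude draw the two attitude counts jointly (multinomial
#'   bootstrap) instead of independent logit-normals.
#' @param continuity_correction rescue boundary proportions by adding 1/2
#'   to successes and failures instead of raising an error.
#' @param keep_draws retain the vector of draws in the result.
#' @return object of class `risk_ratio_estimate`: `species`, `phi_plugin`
#'   (point plug-in at the estimates), `phi_median`, `phi_mean`, `ci_low`,
#'   `ci_high` (percentile 95%), `n_draws`, `seed`, `inputs`, and `draws`
#'   if requested.
#' @export
monte_carlo_risk_ratio <- function(inputs, species, n_draws = 10000,
                                   seed = 20140601,
                                   scale = c("link", "response"),
                                   joint_attitude = FALSE,
                                   continuity_correction = FALSE,
                                   keep_draws = FALSE) {
  scale <- match.arg(scale)
  stopifnot(inherits(inputs, "kill_risk_inputs"))
  if (!species %in% names(inputs$eps)) {
    mr_error(sprintf("no eps entry for species '%s'", species),
             "mimicryrisk_estimability_error")
  }
  if (inputs$mu0$k < 1) {
    mr_error("mu0 has zero successes: phi is undefined at zero baseline",
             "mimicryrisk_domain_error")
  }
  mu0 <- resolve_boundary(inputs$mu0, "mu0", continuity_correction)
  muv <- resolve_boundary(inputs$muv, "muv", continuity_correction)
  e <- inputs$eps[[species]]
  if (!all(is.finite(c(e$eta, e$se_eta)))) {
    mr_error(sprintf("eps for '%s' has a non-finite link-scale estimate or SE",
                     species), "mimicryrisk_boundary_error")
  }

  phi_plugin <- risk_ratio(mu0$p_hat, muv$p_hat, plogis(e$eta))

  draws <- with_local_seed(seed, {
    eps_star <- plogis(rnorm(n_draws, e$eta, e$se_eta))
    if (joint_attitude) {
      n <- mu0$n
      other <- n - mu0$k - muv$k
      ks <- rmultinom(n_draws, n, c(mu0$k, muv$k, other) / n)
      mu0_star <- pmax(ks[1, ] / n, 0.5 / n)
      muv_star <- ks[2, ] / n
    } else if (scale == "link") {
      mu0_star <- plogis(rnorm(n_draws, mu0$eta_hat, mu0$se_eta))
      muv_star <- plogis(rnorm(n_draws, muv$eta_hat, muv$se_eta))
    } else {
      sd0 <- mu0$se_eta * mu0$p_hat * (1 - mu0$p_hat)
      sdv <- muv$se_eta * muv$p_hat * (1 - muv$p_hat)
      mu0_star <- pmin(pmax(rnorm(n_draws, mu0$p_hat, sd0), 1e-12), 1)
      muv_star <- pmin(pmax(rnorm(n_draws, muv$p_hat, sdv), 0), 1)
    }
    1 + (muv_star * eps_star) / mu0_star
  })

  qs <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  structure(list(species = species, phi_plugin = phi_plugin,
                 phi_median = median(draws), phi_mean = mean(draws),
                 ci_low = qs[1], ci_high = qs[2],
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 scale = scale, joint_attitude = joint_attitude,
                 inputs = list(mu0 = mu0$p_hat, muv = muv$p_hat,
                               eps = plogis(e$eta)),
                 draws = if (keep_draws) draws else NULL),
            class = "risk_ratio_estimate")
}

#' @export
print.risk_ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "Kill-risk ratio phi[%s]: median %.3f (mean %.3f, plug-in %.3f), 95%% CI [%.3f, %.3f] (%d draws, seed %d)\n",
    x$species, x$phi_median, x$phi_mean, x$phi_plugin, x$ci_low, x$ci_high,
    x$n_draws, x$seed))
  invisible(x)
}

#' Delta-method approximation to the risk-ratio uncertainty
#'
#' Independent first-order (delta-method) cross-check of the Monte Carlo:
#' writing `g = muv * eps / mu0` so `phi = 1 + g`, and differentiating
#' `log(phi)` with respect to each logit-scale parameter
#' (`d p / d eta = p (1 - p)`), the variance of `log(phi)` is
#' \deqn{\left(\frac{g}{\phi}\right)^2\Big[(1-\mu_v)^2 s_v^2
#'   + (1-\varepsilon)^2 s_\varepsilon^2 + (1-\mu_0)^2 s_0^2\Big]}
#' with the three logit-scale SEs `s`. The interval is lognormal:
#' `phi * exp(+-1.96 * se_log_phi)`.
#'
#' @inheritParams monte_carlo_risk_ratio
#' @return list with `species`, `phi` (plug-in), `se_log_phi`, `ci_low`,
#'   `ci_high`.
#' @export
delta_method_risk_ratio <- function(inputs, species,
                                    continuity_correction = FALSE) {
  stopifnot(inherits(inputs, "kill_risk_inputs"))
  mu0 <- resolve_boundary(inputs$mu0, "mu0", continuity_correction)
  muv <- resolve_boundary(inputs$muv, "muv", continuity_correction)
  e <- inputs$eps[[species]]
  if (is.null(e)) {
    mr_error(sprintf("no eps entry for species '%s'", species),
             "mimicryrisk_estimability_error")
  }
  p0 <- mu0$p_hat
  pv <- muv$p_hat
  pe <- plogis(e$eta)
  g <- pv * pe / p0
  phi <- 1 + g
  se_log_phi <- (g / phi) * sqrt((1 - pv)^2 * muv$se_eta^2 +
                                   (1 - pe)^2 * e$se_eta^2 +
                                   (1 - p0)^2 * mu0$se_eta^2)
  z <- qnorm(0.975)
  list(species = species, phi = phi, se_log_phi = se_log_phi,
       ci_low = phi * exp(-z * se_log_phi),
       ci_high = phi * exp(z * se_log_phi))
}
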