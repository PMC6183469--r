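#' Intercept-only binomial GLM for a proportion
#'
#' The maximum-likelihood fit of a logit-link binomial GLM with only an
#' intercept has a closed form: the estimate is `logit(k/n)` and the
#' standard error of the intercept is `sqrt(1/k + 1/(n - k))` (the inverse
#' Fisher information of the logit at the MLE). The 95% interval is Wald on
#' the logit scale, back-transformed, so it respects the [0, 1] support.
#'
#' Boundary cases `k = 0` or `k = n` have an infinite logit MLE; `p_hat` is
#' still returned but `eta_hat`/`se_eta` are non-finite and the interval is
#' computed from the continuity-corrected fit (`k + 1/2` successes,
#' `n - k + 1/2` failures), with `boundary = TRUE` flagging the correction.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf_level confidence level, default 0.95.
#' @return object of class `proportion_estimate`: list with `k`, `n`,
#'   `p_hat`, `eta_hat`, `se_eta`, `ci_low`, `ci_high`, `boundary`.
#' @examples
#' fit_intercept_glm(10, 102)  # baseline kill proportion at study scale
#' @export
fit_intercept_glm <- function(k, n, conf_level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n)) {
    mr_error("k and n must be single non-missing counts", "mimicryrisk_schema_error")
  }
  if (n < 1) mr_error("n must be >= 1 (no trials observed)", "mimicryrisk_empty_input_error")
  if (k < 0 || k > n) mr_error("k must satisfy 0 <= k <= n", "mimicryrisk_schema_error")
  z <- qnorm(1 - (1 - conf_level) / 2)
  p_hat <- k / n
  boundary <- (k == 0 || k == n)
  if (!boundary) {
    eta <- qlogis(p_hat)
    se <- sqrt(1 / k + 1 / (n - k))
    ci <- plogis(eta + c(-1, 1) * z * se)
  } else {
    eta <- if (k == 0) -Inf else Inf
    se <- Inf
    # continuity-corrected interval so the invariant ci_low <= p <= ci_high
    # still holds at the boundary
    kc <- k + 0.5
    nc <- n + 1
    etac <- qlogis(kc / nc)
    sec <- sqrt(1 / kc + 1 / (nc - kc))
    ci <- plogis(etac + c(-1, 1) * z * sec)
    ci <- c(min(ci[1], p_hat), max(ci[2], p_hat))
  }
  structure(list(k = as.integer(k), n = as.integer(n), p_hat = p_hat,
                 eta_hat = eta, se_eta = se,
                 ci_low = ci[1], ci_high = ci[2], boundary = boundary),
            class = "proportion_estimate")
}

#' Continuity-correct a boundary proportion estimate
#'
#' Adds half a success and half a failure (so `k + 1/2` out of `n + 1`) and
#' refits, giving finite logit-scale quantities when `k` is 0 or `n`. Used
#' by the Monte Carlo sampler when asked to rescue a boundary estimate.
#'
#' @param est a [fit_intercept_glm()] result.
#' @return a `proportion_estimate` with finite `eta_hat` and `se_eta`.
#' @export
continuity_correct <- function(est) {
  stopifnot(inherits(est, "proportion_estimate"))
  kc <- est$k + 0.5
  nc <- est$n + 1
  eta <- qlogis(kc / nc)
  se <- sqrt(1 / kc + 1 / (nc - kc))
  z <- qnorm(0.975)
  structure(list(k = est$k, n = est$n, p_hat = kc / nc, eta_hat = eta,
                 se_eta = se, ci_low = plogis(eta - z * se),
                 ci_high = plogis(eta + z * se), boundary = FALSE),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("Proportion %d/%d = %.4f (logit %.4f, SE %.4f), 95%% CI [%.4f, %.4f]%s\n",
              x$k, x$n, x$p_hat, x$eta_hat, x$se_eta, x$ci_low, x$ci_high,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}
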