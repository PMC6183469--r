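#' Specify a binomial identification GLMM
#'
#' The identification analysis uses two model families on the trial table:
#' * `response = "called_adder"`: probability a picture is identified as an
#'   adder, with the true species as the fixed factor (adder = intercept).
#' * `response = "mistake"`: probability of a wrong-species answer, with
#'   respondent attitude as the fixed factor (kill_selective = intercept).
#'
#' Both include crossed random intercepts for picture and respondent, which
#' absorb picture-to-picture difficulty and person-to-person skill.
#'
#' @param response `"called_adder"` or `"mistake"`.
#' @param fixed_factor `"species"` or `"attitude"`; defaults to the factor
#'   conventionally paired with the response.
#' @param reference_level level coded as the intercept; defaults to
#'   `"adder"` for species and `"kill_selective"` for attitude.
#' @param subset_attitude optional attitude level(s); only respondents with
#'   these attitudes enter the fit (the misidentification probabilities
#'   eps_i use the `"kill_selective"` subset).
#' @param unknown_as_mistake count `"unknown"` answers as mistakes instead
#'   of dropping them (mistake response only).
#' @param drop_unknown_for_adder_model drop `"unknown"` answers from the
#'   called-adder model instead of scoring them as "not called adder".
#' @return object of class `glmm_spec`.
#' @export
glmm_spec <- function(response = c("called_adder", "mistake"),
                      fixed_factor = NULL, reference_level = NULL,
                      subset_attitude = NULL,
                      unknown_as_mistake = FALSE,
                      drop_unknown_for_adder_model = FALSE) {
  response <- match.arg(response)
  if (is.null(fixed_factor)) {
    fixed_factor <- if (response == "called_adder") "species" else "attitude"
  }
  fixed_factor <- match.arg(fixed_factor, c("species", "attitude"))
  lev <- if (fixed_factor == "species") species_levels() else attitude_levels()
  if (is.null(reference_level)) {
    reference_level <- if (fixed_factor == "species") "adder" else "kill_selective"
  }
  if (!reference_level %in% lev) {
    mr_error(sprintf("reference_level '%s' is not a level of %s",
                     reference_level, fixed_factor),
             "mimicryrisk_estimability_error")
  }
  if (!is.null(subset_attitude) &&
      !all(subset_attitude %in% attitude_levels())) {
    mr_error("subset_attitude must be attitude levels", "mimicryrisk_schema_error")
  }
  structure(list(response = response, fixed_factor = fixed_factor,
                 reference_level = reference_level,
                 subset_attitude = subset_attitude,
                 unknown_as_mistake = unknown_as_mistake,
                 drop_unknown_for_adder_model = drop_unknown_for_adder_model),
            class = "glmm_spec")
}

#' Control parameters for the GLMM fitter
#'
#' @param outer_grad_tol projected-gradient tolerance (log-variance scale)
#'   required to declare convergence. The gradient is finite-differenced,
#'   which bounds how small a tolerance can be certified in practice.
#' @param inner_tol max absolute penalized-score tolerance for the joint
#'   (beta, u) mode.
#' @param max_outer,max_inner iteration caps.
#' @param var_floor lower bound for the variance components; a component at
#'   the floor is reported in `boundary_flags`.
#' @param var_start starting value for both variance components.
#' @return list of class `glmm_control`.
#' @export
glmm_control <- function(outer_grad_tol = 5e-4, inner_tol = 1e-8,
                         max_outer = 200, max_inner = 80,
                         var_floor = 1e-10, var_start = 0.5) {
  structure(list(outer_grad_tol = outer_grad_tol, inner_tol = inner_tol,
                 max_outer = max_outer, max_inner = max_inner,
                 var_floor = var_floor, var_start = var_start),
            class = "glmm_control")
}

# Assemble the model frame (response, fixed factor, grouping factors) for a
# spec, applying the unknown-response conventions.
build_glmm_frame <- function(dataset, spec) {
  t <- dataset$trials
  r <- dataset$respondents
  att <- setNames(r$attitude, r$respondent_id)
  t$attitude <- att[t$respondent_id]

  if (!is.null(spec$subset_attitude)) {
    t <- t[t$attitude %in% spec$subset_attitude, , drop = FALSE]
  }

  if (spec$response == "called_adder") {
    if (spec$drop_unknown_for_adder_model) {
      t <- t[t$response != "unknown", , drop = FALSE]
    }
    y <- as.integer(t$response == "adder")
  } else {
    if (!spec$unknown_as_mistake) {
      t <- t[t$response != "unknown", , drop = FALSE]
      y <- as.integer(t$response != t$true_species)
    } else {
      y <- as.integer(t$response != t$true_species)  # unknown counts wrong
    }
  }

  lev <- if (spec$fixed_factor == "species") species_levels() else attitude_levels()
  xval <- if (spec$fixed_factor == "species") t$true_species else t$attitude
  lev_ord <- c(spec$reference_level, setdiff(lev, spec$reference_level))
  x <- factor(xval, levels = lev_ord)

  present <- lev_ord %in% unique(xval)
  if (!all(present)) {
    mr_error(sprintf(
      "fixed-factor level(s) absent from the data after subsetting: %s",
      paste(lev_ord[!present], collapse = ", ")),
      "mimicryrisk_estimability_error")
  }
  list(y = y, x = x,
       picture = factor(t$picture_id),
       respondent = factor(t$respondent_id),
       n_obs = length(y))
}

#' Fit a binomial logit GLMM with crossed random intercepts
#'
#' Maximum-likelihood fit (not REML) of
#' \deqn{y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(X\beta + a_{pic} + b_{resp}))}
#' with \eqn{a \sim N(0, \sigma^2_{pic})}, \eqn{b \sim N(0, \sigma^2_{resp})},
#' using the Laplace approximation to the marginal likelihood: a penalized
#' iteratively reweighted least squares inner loop finds the joint mode of
#' (beta, random effects) for given variances, and a quasi-Newton outer
#' optimizer maximizes the Laplace log-likelihood over the log-variances.
#' This mirrors the default fitting approach of mixed-model software for
#' binomial responses.
#'
#' @param dataset a [survey_dataset()].
#' @param spec a [glmm_spec()].
#' @param control a [glmm_control()].
#' @param fix_variance optional named numeric, e.g.
#'   `c(picture = 0, respondent = 0)`, fixing a component instead of
#'   estimating it (variance 0 reduces the model to an ordinary logistic
#'   GLM for the fixed effects).
#' @return object of class `glmm_fit` with elements `beta` (named,
#'   intercept = reference level), `vcov_beta`, `var_picture`,
#'   `var_respondent`, `loglik` (Laplace-approximate marginal), `converged`,
#'   `boundary_flags`, `n_obs`, `n_pictures`, `n_respondents`, `warnings`,
#'   `spec`.
#' @seealso [population_probability()], [fit_mistake_model()]
#' @export
fit_binomial_glmm <- function(dataset, spec = glmm_spec(),
                              control = glmm_control(),
                              fix_variance = NULL) {
  fr <- build_glmm_frame(dataset, spec)
  q1 <- nlevels(fr$picture)
  q2 <- nlevels(fr$respondent)
  if (q1 < 2 || q2 < 2) {
    mr_error("need at least 2 pictures and 2 respondents to fit random intercepts",
             "mimicryrisk_estimability_error")
  }
  X <- model.matrix(~x, data = list(x = fr$x))
  fit <- laplace_glmm_core(fr$y, X, as.integer(fr$picture),
                           as.integer(fr$respondent), q1, q2,
                           control, fix_variance)

  lev_ord <- levels(fr$x)
  nm <- c(paste0("(Intercept:", lev_ord[1], ")"), lev_ord[-1])
  beta <- setNames(fit$beta, nm)
  vb <- fit$vcov_beta
  dimnames(vb) <- list(nm, nm)
  structure(list(beta = beta, vcov_beta = vb,
                 var_picture = fit$var[1], var_respondent = fit$var[2],
                 loglik = fit$loglik, converged = fit$converged,
                 boundary_flags = fit$boundary_flags,
                 n_obs = fr$n_obs, n_pictures = q1, n_respondents = q2,
                 warnings = fit$warnings,
                 levels = lev_ord, reference_level = lev_ord[1],
                 spec = spec, control = control),
            class = "glmm_fit")
}

# Core Laplace fitter, independent of the survey data model.
# y: 0/1 vector; X dense fixed-effect design; ip/ir integer indices mapping
# each observation to its picture (1..q1) and respondent (1..q2) level.
# Scaled parameterization u = sigma * v with v ~ N(0, I), so a variance of
# exactly 0 is a regular point (the model degenerates to a GLM).
#
# The marginal likelihood is approximated by Laplace over the random
# effects only: for candidate (beta, sigma) the inner PIRLS loop finds the
# conditional mode of v, and
#   logL ~= l(y | beta, v_hat) - v_hat'v_hat/2 - log det(Zs'W Zs + I)/2.
# The outer quasi-Newton optimization runs over (log-variances, beta)
# jointly; profiling beta at the penalized joint mode instead (the PQL-like
# shortcut) attenuates fixed effects noticeably for binary responses with
# few trials per cluster, so it is not used.
#
# Because every observation carries exactly one picture and one respondent,
# the penalized curvature M = Zs'W Zs + I has the two-block arrow form
#   M = [ Dp  C ; C' Dr ]
# with Dp, Dr diagonal and C the q1 x q2 weight cross-tabulation. All
# solves and the log-determinant reduce to dense algebra in the (small)
# picture dimension via the Schur complement S = Dp - C Dr^{-1} C':
#   log det M = sum(log Dr) + log det S.
# This keeps the fit fast even with thousands of respondents.
laplace_glmm_core <- function(y, X, ip, ir, q1, q2, control,
                              fix_variance = NULL) {
  p <- ncol(X)
  q <- q1 + q2
  n <- length(y)
  warnings <- character(0)

  fixed <- c(picture = NA_real_, respondent = NA_real_)
  if (!is.null(fix_variance)) {
    fixed[names(fix_variance)] <- as.numeric(fix_variance)
  }
  free <- is.na(fixed)

  # starting values: plain GLM for beta, v = 0
  beta0 <- tryCatch(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  state <- new.env(parent = emptyenv())
  state$v <- rep(0, q)
  state$inner_ok <- TRUE

  clamp <- function(mu) pmin(pmax(mu, 1e-12), 1 - 1e-12)
  inner_tol <- control$inner_tol * max(1, n / 100)
  idx1 <- which(y == 1L)
  # Bernoulli log-likelihood straight from the linear predictor:
  # sum_i [y_i eta_i - log(1 + exp(eta_i))], with the softplus written as
  # max(eta, 0) + log1p(exp(-|eta|)) for stability at extreme eta
  bern_ll <- function(eta) {
    sum(eta[idx1]) - sum(pmax(eta, 0)) - sum(log1p(exp(-abs(eta))))
  }
  # Group sums use a one-pass C aggregation.
  sum_by_pic <- function(x) {
    out <- numeric(q1)
    o <- rowsum(x, ip)
    out[as.integer(rownames(o))] <- o
    out
  }
  sum_by_resp <- function(x) {
    out <- numeric(q2)
    o <- rowsum(x, ir)
    out[as.integer(rownames(o))] <- o
    out
  }
  # cross-tab scatter: cells are precomputed; most surveys have exactly one
  # observation per (picture, respondent) pair, but duplicates are summed
  cell <- (ir - 1L) * q1 + ip
  has_dup <- anyDuplicated(cell) > 0
  ucell <- if (has_dup) sort(unique(cell)) else cell
  cgrp <- if (has_dup) match(cell, ucell) else NULL

  # factorization of M for a weight vector w at scales (s1, s2):
  # returns solve/logdet closures
  factor_M <- function(w, s1, s2) {
    Dp <- 1 + s1^2 * sum_by_pic(w)
    Dr <- 1 + s2^2 * sum_by_resp(w)
    Cm <- matrix(0, q1, q2)
    if (has_dup) {
      Cm[ucell] <- rowsum(w, cgrp)
    } else {
      Cm[cell] <- w
    }
    Cm <- s1 * s2 * Cm
    S <- -Cm %*% (t(Cm) / Dr)
    diag(S) <- diag(S) + Dp
    Rs <- chol(S)
    list(
      solve = function(gp, gr) {
        # gp: q1 vector or q1 x k matrix; gr likewise
        t1 <- gr / Dr
        rhs <- gp - Cm %*% t1
        xp <- backsolve(Rs, forwardsolve(t(Rs), rhs))
        xr <- (gr - crossprod(Cm, xp)) / Dr
        list(p = xp, r = xr)
      },
      logdet = sum(log(Dr)) + 2 * sum(log(diag(Rs))))
  }

  # conditional mode of the scaled random effects v for given (sigma, beta)
  pirls_v <- function(sig, beta) {
    s1 <- sig[1]; s2 <- sig[2]
    off <- as.vector(X %*% beta)
    v <- state$v
    a <- v[seq_len(q1)]; b <- v[q1 + seq_len(q2)]
    eta <- off + s1 * a[ip] + s2 * b[ir]
    mu <- plogis(eta)
    obj <- bern_ll(eta) - 0.5 * (sum(a^2) + sum(b^2))
    inner_ok <- FALSE
    for (it in seq_len(control$max_inner)) {
      r <- y - mu
      gp <- s1 * sum_by_pic(r) - a
      gr <- s2 * sum_by_resp(r) - b
      if (max(abs(c(gp, gr))) < inner_tol) {
        inner_ok <- TRUE
        break
      }
      w <- pmax(mu * (1 - mu), 1e-12)
      fac <- factor_M(w, s1, s2)
      d <- fac$solve(gp, gr)
      dp <- as.vector(d$p); dr <- as.vector(d$r)
      step <- 1
      repeat {
        ca <- a + step * dp
        cb <- b + step * dr
        eta_c <- off + s1 * ca[ip] + s2 * cb[ir]
        obj_c <- bern_ll(eta_c) - 0.5 * (sum(ca^2) + sum(cb^2))
        if (is.finite(obj_c) && obj_c >= obj - 1e-10) break
        step <- step / 2
        if (step < 1e-10) break
      }
      a <- ca; b <- cb; eta <- eta_c; obj <- obj_c
      mu <- plogis(eta)
    }
    state$v <- c(a, b)  # warm start across outer evaluations
    state$inner_ok <- inner_ok
    w <- pmax(mu * (1 - mu), 1e-12)
    fac <- factor_M(w, s1, s2)
    list(loglik = obj - 0.5 * fac$logdet, v = c(a, b), w = w, mu = mu,
         fac = fac, sig = c(s1, s2))
  }

  sum_mat_by <- function(x, idx, qk) {
    o <- rowsum(x, idx)
    out <- matrix(0, qk, ncol(x))
    out[as.integer(rownames(o)), ] <- o
    out
  }

  # joint Newton over (beta, v) for given sigma: the fast PQL-style pass
  # used only to produce good starting values for the true Laplace
  # optimization (its beta is attenuated for binary data, so it is never
  # reported)
  pirls_joint <- function(sig) {
    s1 <- sig[1]; s2 <- sig[2]
    beta <- state$beta
    v <- state$v
    a <- v[seq_len(q1)]; b <- v[q1 + seq_len(q2)]
    eta <- as.vector(X %*% beta) + s1 * a[ip] + s2 * b[ir]
    mu <- plogis(eta)
    obj <- bern_ll(eta) - 0.5 * (sum(a^2) + sum(b^2))
    for (it in seq_len(control$max_inner)) {
      r <- y - mu
      gb <- as.vector(crossprod(X, r))
      gp <- s1 * sum_by_pic(r) - a
      gr <- s2 * sum_by_resp(r) - b
      if (max(abs(c(gb, gp, gr))) < inner_tol) break
      w <- pmax(mu * (1 - mu), 1e-12)
      fac <- factor_M(w, s1, s2)
      Bp <- s1 * sum_mat_by(X * w, ip, q1)
      Br <- s2 * sum_mat_by(X * w, ir, q2)
      solB <- fac$solve(Bp, Br)
      Hbb <- crossprod(X * sqrt(w)) - crossprod(Bp, solB$p) -
        crossprod(Br, solB$r)
      solg <- fac$solve(gp, gr)
      db <- solve(Hbb, gb - as.vector(crossprod(Bp, solg$p)) -
                    as.vector(crossprod(Br, solg$r)))
      # dv = M^{-1}(gv - B db)
      solv <- fac$solve(gp - Bp %*% db, gr - Br %*% db)
      dp <- as.vector(solv$p); dr <- as.vector(solv$r)
      step <- 1
      repeat {
        cbeta <- beta + step * db
        ca <- a + step * dp
        cb <- b + step * dr
        eta_c <- as.vector(X %*% cbeta) + s1 * ca[ip] + s2 * cb[ir]
        obj_c <- bern_ll(eta_c) - 0.5 * (sum(ca^2) + sum(cb^2))
        if (is.finite(obj_c) && obj_c >= obj - 1e-10) break
        step <- step / 2
        if (step < 1e-10) break
      }
      beta <- cbeta; a <- ca; b <- cb; eta <- eta_c; obj <- obj_c
      mu <- plogis(eta)
    }
    state$beta <- beta
    state$v <- c(a, b)
    w <- pmax(mu * (1 - mu), 1e-12)
    fac <- factor_M(w, s1, s2)
    list(loglik = obj - 0.5 * fac$logdet, beta = beta)
  }

  nfree <- sum(free)
  split_par <- function(par) {
    var_all <- fixed
    if (nfree > 0) var_all[free] <- exp(par[seq_len(nfree)])
    list(var = var_all, beta = par[nfree + seq_len(p)])
  }
  negll <- function(par) {
    sp <- split_par(par)
    -pirls_v(sqrt(pmax(sp$var, 0)), sp$beta)$loglik
  }

  if (all(!free) && all(fixed == 0)) {
    # degenerate case: both variances fixed at 0 is an ordinary logistic
    # GLM; fit it by IRLS directly so the agreement is exact
    gfit <- stats::glm.fit(X, y, family = stats::binomial(),
                           control = stats::glm.control(epsilon = 1e-12))
    beta <- gfit$coefficients
    mu <- clamp(plogis(as.vector(X %*% beta)))
    w <- pmax(mu * (1 - mu), 1e-12)
    var_all <- fixed
    opt_ok <- gfit$converged
    grad_ok <- TRUE
    inner_ok <- TRUE
    loglik <- sum(dbinom(y, 1, mu, log = TRUE))
    v_hat <- rep(0, q)
    final_fac <- factor_M(w, 0, 0)
  } else {
    # stage 1: joint-mode profile over the free log-variances only (cheap,
    # 2-dimensional) to land near the optimum
    state$beta <- beta0
    theta0 <- rep(log(control$var_start), nfree)
    if (nfree > 0) {
      opt0 <- optim(theta0, function(th) {
        var_all <- fixed
        var_all[free] <- exp(th)
        -pirls_joint(sqrt(pmax(var_all, 0)))$loglik
      }, method = if (nfree > 1) "Nelder-Mead" else "Brent",
      lower = if (nfree > 1) -Inf else log(control$var_floor),
      upper = if (nfree > 1) Inf else log(1e6),
      control = list(maxit = 100, reltol = 1e-6))
      theta0 <- pmax(opt0$par, log(control$var_floor))
      var_tmp <- fixed
      var_tmp[free] <- exp(theta0)
      beta_start <- pirls_joint(sqrt(pmax(var_tmp, 0)))$beta
    } else {
      beta_start <- pirls_joint(sqrt(pmax(fixed, 0)))$beta
    }
    # stage 2: true Laplace objective over (log-variances, beta)
    start <- c(theta0, beta_start)
    lower <- c(rep(log(control$var_floor), nfree), rep(-30, p))
    upper <- c(rep(log(1e6), nfree), rep(30, p))
    opt <- optim(start, negll, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = control$max_outer, factr = 1e8))
    sp <- split_par(opt$par)
    var_all <- sp$var
    beta <- sp$beta
    opt_ok <- opt$convergence == 0
    # projected finite-difference gradient over the free log-variances
    grad_ok <- TRUE
    if (nfree > 0) {
      h <- 1e-3
      gproj <- vapply(seq_len(nfree), function(j) {
        pj <- opt$par
        if (pj[j] - h < log(control$var_floor)) {
          pj2 <- pj; pj2[j] <- pj[j] + h
          min((negll(pj2) - negll(pj)) / h, 0)  # only descent counts at bound
        } else {
          pm <- pj; pm[j] <- pj[j] - h
          pp <- pj; pp[j] <- pj[j] + h
          (negll(pp) - negll(pm)) / (2 * h)
        }
      }, numeric(1))
      grad_ok <- max(abs(gproj)) < control$outer_grad_tol * max(1, n / 100)
    }
    final <- pirls_v(sqrt(pmax(var_all, 0)), beta)
    loglik <- final$loglik
    inner_ok <- state$inner_ok
    w <- final$w
    v_hat <- final$v
    final_fac <- final$fac
  }

  if (any(abs(beta) > 15)) {
    warnings <- c(warnings,
      "large fixed-effect estimate: possible complete separation in a cell")
  }

  # covariance of beta: top-left block of the inverse joint (beta, v)
  # Hessian, i.e. (X'WX - B' M^{-1} B)^{-1} with B = Zs'WX
  s1 <- sqrt(pmax(var_all[[1]], 0))
  s2 <- sqrt(pmax(var_all[[2]], 0))
  XWX <- crossprod(X * sqrt(w))
  sum_mat_by <- function(x, idx, qk) {
    o <- rowsum(x, idx)
    out <- matrix(0, qk, ncol(x))
    out[as.integer(rownames(o)), ] <- o
    out
  }
  Bp <- s1 * sum_mat_by(X * w, ip, q1)
  Br <- s2 * sum_mat_by(X * w, ir, q2)
  sol <- final_fac$solve(Bp, Br)
  Hbb <- XWX - crossprod(Bp, sol$p) - crossprod(Br, sol$r)
  Vfull <- tryCatch(solve(Hbb), error = function(e) matrix(NA_real_, p, p))
  vcov_beta <- (Vfull + t(Vfull)) / 2

  boundary <- character(0)
  if (free[["picture"]] && var_all[["picture"]] <= 2 * control$var_floor) {
    boundary <- c(boundary, "picture")
  }
  if (free[["respondent"]] && var_all[["respondent"]] <= 2 * control$var_floor) {
    boundary <- c(boundary, "respondent")
  }

  list(beta = beta, vcov_beta = vcov_beta,
       var = unname(var_all), loglik = loglik,
       converged = opt_ok && inner_ok && grad_ok,
       boundary_flags = boundary, warnings = warnings,
       ranef_scaled = v_hat)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Binomial GLMM (%s ~ %s + (1|picture) + (1|respondent)), Laplace ML\n",
              x$spec$response, x$spec$fixed_factor))
  if (!is.null(x$spec$subset_attitude)) {
    cat(sprintf("  subset: attitude in {%s}\n",
                paste(x$spec$subset_attitude, collapse = ", ")))
  }
  cat(sprintf("  n = %d obs, %d pictures, %d respondents\n",
              x$n_obs, x$n_pictures, x$n_respondents))
  se <- sqrt(diag(x$vcov_beta))
  for (i in seq_along(x$beta)) {
    cat(sprintf("  %-24s %8.4f (SE %.4f)\n", names(x$beta)[i], x$beta[i], se[i]))
  }
  cat(sprintf("  var(picture) = %.4f, var(respondent) = %.4f\n",
              x$var_picture, x$var_respondent))
  cat(sprintf("  logLik (Laplace) = %.4f, converged: %s%s\n", x$loglik,
              x$converged,
              if (length(x$boundary_flags)) paste0(" [boundary: ",
                paste(x$boundary_flags, collapse = ", "), "]") else ""))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Recognition probability for a fixed-factor level
#'
#' Back-transforms the linear predictor for a level of the fixed factor.
#' The default (`type = "conditional"`) sets both random intercepts to
#' zero — the probability for an average picture shown to an average
#' respondent, which is how mixed-model fixed effects are conventionally
#' reported. `type = "marginal"` instead integrates the inverse logit over
#' the fitted random-effect distribution (logit-normal, Gauss-Hermite
#' quadrature), approximating the population-averaged rate.
#'
#' @param fit a [fit_binomial_glmm()] result.
#' @param level a level of the fit's fixed factor.
#' @param type `"conditional"` (random effects at zero) or `"marginal"`.
#' @param conf_level confidence level for the Wald interval.
#' @return list with `level`, `eta`, `se_eta` (link scale, from the
#'   fixed-effect covariance), `prob`, `ci_low`, `ci_high`, `type`.
#' @export
population_probability <- function(fit, level, type = c("conditional", "marginal"),
                                   conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "glmm_fit"))
  if (!level %in% fit$levels) {
    mr_error(sprintf("level '%s' is not a fixed-factor level of this fit (%s)",
                     level, paste(fit$levels, collapse = ", ")),
             "mimicryrisk_estimability_error")
  }
  cvec <- as.numeric(fit$levels == level)
  cvec[1] <- 1  # intercept always enters
  eta <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
  z <- qnorm(1 - (1 - conf_level) / 2)
  trans <- function(e) {
    if (type == "conditional") {
      plogis(e)
    } else {
      logit_normal_mean(e, sqrt(fit$var_picture + fit$var_respondent))
    }
  }
  list(level = level, eta = eta, se_eta = se, prob = trans(eta),
       ci_low = trans(eta - z * se), ci_high = trans(eta + z * se),
       type = type)
}

# E[plogis(mu + s*Z)], Z ~ N(0,1), by Gauss-Hermite quadrature.
logit_normal_mean <- function(mu, s, nodes = 41) {
  gh <- gauss_hermite(nodes)
  sum(gh$w * plogis(mu + sqrt(2) * s * gh$x)) / sqrt(pi)
}

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' convention:
# integral of f(x) exp(-x^2) dx ~ sum w_i f(x_i)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- sqrt(pi) * ev$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Attitude-versus-skill mistake model
#'
#' Tests whether identification skill differs by attitude: fits the mistake
#' indicator (wrong species named; `"unknown"` dropped by default) against
#' attitude with the usual crossed picture/respondent random intercepts.
#' Positive contrasts for `no_kill` / `kill_all` mean selective killers
#' make fewer mistakes.
#'
#' @inheritParams fit_binomial_glmm
#' @param unknown_as_mistake score `"unknown"` answers as mistakes.
#' @return a `glmm_fit`.
#' @export
fit_mistake_model <- function(dataset, unknown_as_mistake = FALSE,
                              control = glmm_control()) {
  fit_binomial_glmm(dataset,
                    glmm_spec(response = "mistake",
                              unknown_as_mistake = unknown_as_mistake),
                    control = control)
}

#' Serialize a GLMM fit to JSON
#'
#' @param fit a `glmm_fit`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
glmm_fit_json <- function(fit, path = NULL) {
  obj <- list(
    response = fit$spec$response,
    fixed_factor = fit$spec$fixed_factor,
    beta = as.list(fit$beta),
    vcov_beta = unname(apply(fit$vcov_beta, 1, as.list)),
    var_picture = fit$var_picture,
    var_respondent = fit$var_respondent,
    loglik = fit$loglik,
    converged = fit$converged,
    boundary_flags = fit$boundary_flags,
    n_obs = fit$n_obs)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
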