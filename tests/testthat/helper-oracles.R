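# Independent oracles used across the suite. These deliberately avoid the
# code paths they are used to check.

# Intercept-only logistic regression by explicit iteratively reweighted
# least squares (scalar Newton on the logit).
irls_intercept_oracle <- function(k, n, tol = 1e-12, max_iter = 100) {
  eta <- 0
  for (i in seq_len(max_iter)) {
    p <- plogis(eta)
    w <- n * p * (1 - p)
    score <- k - n * p
    step <- score / w
    eta <- eta + step
    if (abs(step) < tol) break
  }
  list(eta = eta, se = 1 / sqrt(n * plogis(eta) * (1 - plogis(eta))))
}

# Adaptive Gauss-Hermite quadrature for the marginal log-likelihood of a
# Bernoulli-logit model with a single random intercept:
#   y_ij ~ Bern(plogis(x_ij'beta + u_j)), u_j ~ N(0, sigma^2).
# Per group: center nodes at the conditional mode, scale by the local
# curvature, >= 21 nodes. Written directly from the quadrature identity;
# shares nothing with the package's Laplace code path.
agq_loglik_oracle <- function(y, group, X, beta, sigma, nodes = 25) {
  gh <- gh_nodes(nodes)
  off <- as.vector(X %*% beta)
  total <- 0
  for (j in unique(group)) {
    idx <- which(group == j)
    h <- function(u) {
      sum(dbinom(y[idx], 1, plogis(off[idx] + u), log = TRUE)) +
        dnorm(u, 0, sigma, log = TRUE)
    }
    uhat <- optimize(function(u) -h(u), c(-15, 15))$minimum
    eps <- 1e-4
    hpp <- (h(uhat + eps) - 2 * h(uhat) + h(uhat - eps)) / eps^2
    s <- 1 / sqrt(-hpp)
    tk <- uhat + sqrt(2) * s * gh$x
    vals <- vapply(tk, h, numeric(1)) + gh$x^2
    m <- max(vals)
    total <- total + m + log(sqrt(2) * s * sum(gh$w * exp(vals - m)))
  }
  total
}

# Gauss-Hermite nodes/weights by the Golub-Welsch eigenvalue method
# (physicists' weight exp(-x^2)).
gh_nodes <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = ev$values[ord], w = (sqrt(pi) * ev$vectors[1, ]^2)[ord])
}

# Single-random-factor toy data fed straight into the Laplace core with the
# picture component fixed at zero (the "collapsed" second factor).
make_single_factor_toy <- function(m, k, sigma, beta = c(0.3, 0.5), seed = 1) {
  withr::with_seed(seed, {
    g <- rep(seq_len(m), each = k)
    x <- rep(c(0, 1), length.out = m * k)
    u <- rnorm(m, 0, sigma)
    y <- rbinom(m * k, 1, plogis(beta[1] + beta[2] * x + u[g]))
    list(y = y, g = g, X = cbind(1, x),
         ip = rep(c(1L, 2L), length.out = m * k))  # inert collapsed factor
  })
}

fit_single_factor <- function(toy, control = glmm_control()) {
  mimicryrisk:::laplace_glmm_core(toy$y, toy$X, toy$ip, toy$g, 2, max(toy$g),
                                  control, fix_variance = c(picture = 0))
}
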