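test_that("plug-in ratio is exact arithmetic with domain errors", {
  expect_equal(risk_ratio(0.098, 0.206, 0.677),
               (0.098 + 0.206 * 0.677) / 0.098, tolerance = 1e-12)
  expect_equal(risk_ratio(0.098, 0.206, 0), 1)
  expect_equal(risk_ratio(0.098, 0, 0.677), 1)
  expect_error(risk_ratio(0, 0.2, 0.5), "undefined",
               class = "mimicryrisk_domain_error")
  expect_error(risk_ratio(0.1, 1.2, 0.5), class = "mimicryrisk_domain_error")
})

test_that("phi is monotone in each argument and bounded below by 1", {
  grid <- expand.grid(mu0 = c(0.02, 0.1, 0.4), muv = c(0, 0.2, 0.6),
                      eps = c(0, 0.07, 0.68, 1))
  phi <- mapply(risk_ratio, grid$mu0, grid$muv, grid$eps)
  expect_true(all(phi >= 1))
  expect_true(all((phi == 1) == (grid$muv * grid$eps == 0)))
  h <- 1e-6
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      expect_gte(risk_ratio(mu0, muv, min(eps + h, 1)), risk_ratio(mu0, muv, eps))
      expect_gte(risk_ratio(mu0, min(muv + h, 1), eps), risk_ratio(mu0, muv, eps))
      expect_lte(risk_ratio(min(mu0 + h, 1), muv, eps), risk_ratio(mu0, muv, eps))
    })
  }
})

make_inputs <- function(k0 = 10, kv = 21, n = 102, eta_e = qlogis(0.677),
                        se_e = 0.35) {
  kill_risk_inputs(
    mu0 = fit_intercept_glm(k0, n),
    muv = fit_intercept_glm(kv, n),
    eps = list(smooth = list(eta = eta_e, se_eta = se_e),
               grass = list(eta = qlogis(0.072), se_eta = 0.5)))
}

test_that("inputs are validated", {
  expect_error(
    kill_risk_inputs(fit_intercept_glm(10, 102), fit_intercept_glm(21, 100),
                     list()),
    "same respondent total", class = "mimicryrisk_schema_error")
  expect_error(
    kill_risk_inputs(fit_intercept_glm(10, 102), fit_intercept_glm(21, 102),
                     list(smooth = list(eta = 1))),
    class = "mimicryrisk_schema_error")
  expect_error(monte_carlo_risk_ratio(make_inputs(), "adder"),
               class = "mimicryrisk_estimability_error")
})

test_that("degenerate SEs collapse the Monte Carlo to the plug-in", {
  inp <- make_inputs(se_e = 0)
  # zero out the attitude SEs by hand
  inp$mu0$se_eta <- 0
  inp$muv$se_eta <- 0
  mc <- monte_carlo_risk_ratio(inp, "smooth", n_draws = 200, seed = 5)
  expect_equal(mc$ci_low, mc$phi_plugin, tolerance = 1e-12)
  expect_equal(mc$phi_median, mc$phi_plugin, tolerance = 1e-12)
  expect_equal(mc$ci_high, mc$phi_plugin, tolerance = 1e-12)
})

test_that("Monte Carlo is seed-deterministic and stable across seeds", {
  inp <- make_inputs()
  m1 <- monte_carlo_risk_ratio(inp, "smooth", seed = 11)
  m2 <- monte_carlo_risk_ratio(inp, "smooth", seed = 11)
  expect_identical(m1, m2)
  m3 <- monte_carlo_risk_ratio(inp, "smooth", seed = 12)
  expect_false(identical(m1$phi_median, m3$phi_median))
  # 2% median stability across seeds at 10,000 draws
  expect_equal(m3$phi_median, m1$phi_median,
               tolerance = 0.02)
  # RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(monte_carlo_risk_ratio(inp, "smooth", seed = 13))
  expect_identical(.Random.seed, before)
})

test_that("small-SE regime matches the delta-method oracle", {
  inp <- make_inputs(se_e = 0.05)
  inp$mu0$se_eta <- 0.05
  inp$muv$se_eta <- 0.05
  mc <- monte_carlo_risk_ratio(inp, "smooth", n_draws = 50000, seed = 17)
  dm <- delta_method_risk_ratio(inp, "smooth")
  expect_equal(mc$phi_median, dm$phi, tolerance = 0.01)
  mc_width <- log(mc$ci_high / mc$ci_low)
  dm_width <- log(dm$ci_high / dm$ci_low)
  expect_equal(mc_width, dm_width, tolerance = 0.1)
})

test_that("delta method: zero SEs give zero log-SE; skew direction matches", {
  inp <- make_inputs(se_e = 0)
  inp$mu0$se_eta <- 0
  inp$muv$se_eta <- 0
  expect_equal(delta_method_risk_ratio(inp, "smooth")$se_log_phi, 0)

  # eps-dominant uncertainty: back-transform of a wide logit normal at
  # p = 0.677 skews phi left (upper tail shorter than lognormal), so the
  # Monte Carlo upper gap undershoots the symmetric-on-log delta interval
  inp2 <- make_inputs(se_e = 1.0)
  inp2$mu0$se_eta <- 0.01
  inp2$muv$se_eta <- 0.01
  mc <- monte_carlo_risk_ratio(inp2, "smooth", n_draws = 50000, seed = 19)
  dm <- delta_method_risk_ratio(inp2, "smooth")
  mc_up <- mc$ci_high / mc$phi_median
  dm_up <- dm$ci_high / dm$phi
  expect_lt(mc_up, dm_up)
})

test_that("boundary proportions error with advice unless corrected", {
  inp <- kill_risk_inputs(
    mu0 = fit_intercept_glm(0, 50), muv = fit_intercept_glm(10, 50),
    eps = list(smooth = list(eta = 0.5, se_eta = 0.3)))
  expect_error(monte_carlo_risk_ratio(inp, "smooth"),
               class = "mimicryrisk_domain_error")  # k = 0 baseline
  inp2 <- kill_risk_inputs(
    mu0 = fit_intercept_glm(50, 50), muv = fit_intercept_glm(0, 50),
    eps = list(smooth = list(eta = 0.5, se_eta = 0.3)))
  expect_error(monte_carlo_risk_ratio(inp2, "smooth"), "continuity",
               class = "mimicryrisk_boundary_error")
  mc <- monte_carlo_risk_ratio(inp2, "smooth", continuity_correction = TRUE,
                               n_draws = 500, seed = 3)
  expect_true(is.finite(mc$phi_median))
})

test_that("alternative sampling schemes stay near the default", {
  inp <- make_inputs()
  mc_link <- monte_carlo_risk_ratio(inp, "smooth", seed = 23)
  mc_resp <- monte_carlo_risk_ratio(inp, "smooth", seed = 23,
                                    scale = "response")
  mc_joint <- monte_carlo_risk_ratio(inp, "smooth", seed = 23,
                                     joint_attitude = TRUE)
  expect_equal(mc_resp$phi_median, mc_link$phi_median,
               tolerance = 0.1)
  expect_equal(mc_joint$phi_median, mc_link$phi_median,
               tolerance = 0.1)
})
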