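test_that("with no between-bird variance the fit matches ordinary least squares", {
  # seed chosen so the random-intercept variance is estimated at its zero
  # boundary, making the mixed fit collapse onto ordinary least squares
  tab <- toy_night_table(bird_sd = 0, resid_sd = 1, seed = 104)
  spec <- model_spec("min_rest_ts", fixed_terms = c("treatment", "ta"),
                     random = "intercept")
  fit <- quiet(fit_lmm(tab, spec))
  expect_true(fit$singular)
  ols <- lm(min_rest_ts ~ condition + ta, data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("coefficients agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  tab <- toy_night_table()
  spec <- model_spec("min_rest_ts", fixed_terms = c("treatment", "ta", "mass"),
                     random = "intercept")
  fit <- quiet(fit_lmm(tab, spec))
  oracle <- nlme::lme(min_rest_ts ~ condition + ta + mass,
                      random = ~ 1 | bird_id, data = tab, method = "REML")
  expect_equal(fit$coefficients$estimate,
               unname(nlme::fixef(oracle)), tolerance = 1e-4)
  expect_equal(fit$resid_sd, oracle$sigma, tolerance = 1e-4)
})

test_that("variance-partition R2 behaves at its analytic limits", {
  # a fit whose random-intercept variance collapses to zero (singular):
  # marginal equals conditional
  tab <- toy_night_table(bird_sd = 0, seed = 104)
  fit0 <- quiet(fit_lmm(tab, model_spec("min_rest_ts",
                                        fixed_terms = c("treatment", "ta"),
                                        random = "intercept")))
  expect_true(fit0$singular)
  expect_equal(fit0$marginal_r2, fit0$conditional_r2, tolerance = 1e-6)
  # intercept-only fixed part: marginal is zero
  m <- quiet(lmerTest::lmer(min_rest_ts ~ 1 + (1 | bird_id),
                            data = toy_night_table(bird_sd = 1)))
  r2 <- r2_mixed(m)
  expect_equal(unname(r2["marginal_r2"]), 0, tolerance = 1e-10)
  expect_gt(r2["conditional_r2"], 0)
})

test_that("marginal R2 never exceeds conditional R2 across seeded fits", {
  for (s in 1:6) {
    tab <- toy_night_table(seed = 200 + s, bird_sd = runif(1, 0, 1.5))
    fit <- quiet(fit_lmm(tab, model_spec("min_rest_ts", random = "slope")))
    expect_lte(fit$marginal_r2, fit$conditional_r2 + 1e-12)
    expect_gte(fit$marginal_r2, 0)
    expect_lte(fit$conditional_r2, 1)
  }
})

test_that("backward simplification drops null terms but never the treatment", {
  # planted: treatment and ta real; wind, mass, sex null
  tab <- toy_night_table(n_birds = 12, n_nights = 14)
  out <- quiet(simplify_model(tab, model_spec("min_rest_ts", random = "intercept")))
  kept <- out$fit$fixed_terms
  expect_true("treatment" %in% kept)
  expect_true("ta" %in% kept)
  # something null was dropped and logged with its p-value
  expect_gt(nrow(out$dropped), 0)
  expect_true(all(out$dropped$p >= 0.05))

  # constructed table where every term matters: nothing is dropped
  set.seed(11)
  tab2 <- toy_night_table(n_birds = 12, n_nights = 14)
  tab2$min_rest_ts <- tab2$min_rest_ts + 0.1 * tab2$wind +
    2 * tab2$mass + 3 * (tab2$sex == "M")
  out2 <- quiet(simplify_model(tab2, model_spec("min_rest_ts",
                                                random = "intercept")))
  expect_equal(nrow(out2$dropped), 0)
  expect_setequal(out2$fit$fixed_terms,
                  c("treatment", "ta", "wind", "mass", "sex"))
})

test_that("a non-significant protected treatment term is still reported", {
  tab <- toy_night_table(effect = 0.05)  # tiny, non-significant effect
  out <- quiet(simplify_model(tab, model_spec("min_rest_ts", random = "intercept")))
  cf <- out$fit$coefficients
  expect_true("treatment" %in% cf$term)
  expect_gt(cf$p[cf$term == "treatment"], 0.05)
})

test_that("bootstrap intervals bracket the point prediction deterministically", {
  tab <- toy_night_table(n_birds = 8, n_nights = 10)
  fit <- quiet(fit_lmm(tab, model_spec("min_rest_ts",
                                       fixed_terms = c("treatment", "ta"),
                                       random = "intercept")))
  pi1 <- quiet(bootstrap_prediction_intervals(fit, n_boot = 60, seed = 5))
  pi2 <- quiet(bootstrap_prediction_intervals(fit, n_boot = 60, seed = 5))
  expect_identical(pi1, pi2)
  both <- pi1[pi1$condition %in% c("control", "treatment"), ]
  expect_true(all(both$lower <= both$predicted & both$predicted <= both$upper))
  # single-resample degenerate interval collapses onto that resample
  pi0 <- quiet(bootstrap_prediction_intervals(fit, n_boot = 1, seed = 6))
  expect_equal(pi0$lower, pi0$upper, tolerance = 1e-9)
})

test_that("the planted treatment contrast is detected by the bootstrap", {
  tab <- toy_night_table(effect = -1.25)
  fit <- quiet(fit_lmm(tab, model_spec("min_rest_ts",
                                       fixed_terms = c("treatment", "ta"),
                                       random = "slope")))
  pi <- quiet(bootstrap_prediction_intervals(fit, n_boot = 100, seed = 7))
  contrast <- pi[pi$condition == "treatment - control", ]
  expect_lt(contrast$upper, 0)  # interval excludes zero
  expect_equal(contrast$predicted,
               fit$coefficients$estimate[fit$coefficients$term == "treatment"],
               tolerance = 1e-6)
})

test_that("thin tables are rejected with clear preconditions", {
  tab <- toy_night_table(n_birds = 1)
  expect_error(quiet(fit_lmm(tab, model_spec("min_rest_ts"))), "individuals")
  tab2 <- toy_night_table(n_birds = 4, n_nights = 2)[1:8, ]
  expect_error(quiet(fit_lmm(tab2, model_spec("min_rest_ts"))), "observations")
})
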