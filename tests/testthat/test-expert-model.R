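# Weighted Beta regression with an expert random intercept: boundary
# squeeze, fixed-effect oracle agreement, random-effect behaviour, df
# bookkeeping.

test_that("the boundary squeeze compresses toward one half exactly as stated", {
  expect_equal(squeeze_probabilities(0.5, 60), 0.5)
  expect_equal(squeeze_probabilities(0.5, 7), 0.5)
  expect_equal(squeeze_probabilities(1, 60), 59.5 / 60)
  expect_equal(squeeze_probabilities(0, 60), 0.5 / 60)
  p <- seq(0, 1, by = 0.125)
  expect_true(all(squeeze_probabilities(p, 10) > 0 & squeeze_probabilities(p, 10) < 1))
})

test_that("constant one-half responses give a near-zero intercept", {
  cov <- small_covariates(30, seed = 201)
  el <- data.frame(
    expert_id = rep(1:3, each = 10), site_id = rep(cov$site_id[1:10], 3),
    p_min = 0.4, p_mode = 0.5, p_max = 0.6,
    presence_confidence = "quite_sure",
    p_suitability = 0.5, suitability_confidence = "quite_sure",
    weight = 0.75
  )
  fit <- suppressWarnings(
    fit_expert(el, cov, reference_scaling(cov), sigma = 0)
  )
  expect_equal(unname(fit$coef["(Intercept)"]), 0, tolerance = 1e-6)
})

test_that("with sigma fixed at zero the fit matches independent optimizers", {
  cov <- small_covariates(20, seed = 202)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 202, sigma_expert = 0, phi = 20)
  el <- simulate_elicitation(cov, truth, n_experts = 1, seed = 202, ref = ref)
  el <- el[1:20, ]
  fit <- suppressWarnings(fit_expert(
    el, cov, ref,
    sigma = 0, vars = c("fpc", "dist_water")
  ))
  y <- squeeze_probabilities(el$p_suitability, nrow(el))
  want <- oracle_weighted_beta(
    fit$X, y, el$weight,
    start = c(unname(fit$coef), log(fit$aux$phi)) * 0.9
  )
  expect_equal(unname(fit$coef), unname(want$beta), tolerance = 1e-5)
  expect_equal(fit$aux$phi, want$phi, tolerance = 1e-4)
  expect_equal(fit$residual_df, nrow(el) - 3)
  expect_equal(fit$edf_random, 0)
})

test_that("the sigma = 0 fit agrees with a weighted Beta GAM cross-check", {
  skip_if_not_installed("mgcv")
  cov <- small_covariates(80, seed = 203)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 203, sigma_expert = 0, phi = 25)
  el <- simulate_elicitation(cov, truth, n_experts = 1, seed = 203, ref = ref)
  fit <- suppressWarnings(fit_expert(el, cov, ref, sigma = 0))
  z <- standardize(cov[match(el$site_id, cov$site_id), ], ref)
  dat <- cbind(
    y = squeeze_probabilities(el$p_suitability, nrow(el)),
    z[sdm_covariates()], w = el$weight
  )
  g <- mgcv::gam(
    y ~ longitude + latitude + fpc + rev + dist_path + dist_water,
    family = mgcv::betar(link = "logit"), weights = w, data = dat
  )
  expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 0.01)
})

test_that("weight rescaling leaves the fixed-effect estimates unchanged (sigma = 0)", {
  cov <- small_covariates(40, seed = 204)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 204, sigma_expert = 0)
  el <- simulate_elicitation(cov, truth, n_experts = 1, seed = 204, ref = ref)
  f1 <- suppressWarnings(fit_expert(el, cov, ref, sigma = 0))
  f2 <- suppressWarnings(fit_expert(el, cov, ref,
    sigma = 0,
    weights = el$weight / 2
  ))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-5)
  expect_equal(f1$aux$phi, f2$aux$phi, tolerance = 1e-3)
})

test_that("the marginal-ML mixed fit agrees with a Laplace GLMM cross-check", {
  skip_if_not_installed("glmmTMB")
  cov <- small_covariates(90, seed = 205)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 205, sigma_expert = 0.6, phi = 30)
  el <- simulate_elicitation(cov, truth, n_experts = 6, seed = 205, ref = ref)
  fit <- fit_expert(el, cov, ref, weights = rep(1, nrow(el)))
  z <- standardize(cov[match(el$site_id, cov$site_id), ], ref)
  dat <- cbind(
    y = squeeze_probabilities(el$p_suitability, nrow(el)),
    z[sdm_covariates()], expert = factor(el$expert_id)
  )
  tmb <- glmmTMB::glmmTMB(
    y ~ longitude + latitude + fpc + rev + dist_path + dist_water + (1 | expert),
    family = glmmTMB::beta_family(link = "logit"), data = dat
  )
  expect_equal(unname(fit$coef), unname(glmmTMB::fixef(tmb)$cond), tolerance = 0.02)
  expect_equal(
    unname(fit$aux$sigma_expert),
    unname(sqrt(glmmTMB::VarCorr(tmb)$cond$expert[1, 1])),
    tolerance = 0.05
  )
  expect_equal(unname(fit$aux$phi), unname(glmmTMB::sigma(tmb)), tolerance = 0.5)
})

test_that("residual df bookkeeping follows both conventions and bounds the random edf", {
  # forced arithmetic
  fake <- structure(
    list(coef = rep(0, 7), n_obs = 60, edf_random = 0),
    class = "sdm_fit"
  )
  expect_equal(residual_df_expert(fake), 53)
  fake$edf_random <- 5
  expect_equal(residual_df_expert(fake), 48)
  expect_equal(residual_df_expert(fake, method = "nominal"), 53)

  # strong expert effects: edf in (0, n_experts - 1]
  cov <- small_covariates(60, seed = 206)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 206, sigma_expert = 1.5, phi = 60)
  el <- simulate_elicitation(cov, truth, n_experts = 6, seed = 206, ref = ref)
  fit <- fit_expert(el, cov, ref)
  expect_gt(fit$edf_random, 0)
  expect_lte(fit$edf_random, 5)
  expect_equal(fit$residual_df, fit$n_obs - 7 - fit$edf_random)
  # nominal convention via the accessor
  expect_equal(residual_df_expert(fit, "nominal"), fit$n_obs - 7)
})

test_that("a single expert falls back to a fixed-intercept fit with a warning", {
  cov <- small_covariates(30, seed = 207)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 207, sigma_expert = 0)
  el <- simulate_elicitation(cov, truth, n_experts = 1, seed = 207, ref = ref)
  expect_warning(fit <- fit_expert(el, cov, ref), "fewer than 2 experts")
  expect_equal(fit$aux$sigma_expert, 0)
  expect_true(fit$converged)
})

test_that("large precision with no expert effect approaches the logit-scale WLS fit", {
  cov <- small_covariates(150, seed = 208)
  ref <- reference_scaling(cov)
  truth <- sdm_truth(seed = 208, sigma_expert = 0, phi = 4000)
  el <- simulate_elicitation(cov, truth, n_experts = 1, seed = 208, ref = ref)
  fit <- suppressWarnings(fit_expert(el, cov, ref, sigma = 0))
  z <- standardize(cov[match(el$site_id, cov$site_id), ], ref)
  X <- sdmfuse:::sdm_design_matrix(z)
  ystar <- qlogis(squeeze_probabilities(el$p_suitability, nrow(el)))
  wls <- lm.wfit(X, ystar, el$weight)$coefficients
  expect_equal(unname(fit$coef), unname(wls), tolerance = 0.02)
})
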