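test_that("imputation leaves complete data untouched and fills all gaps", {
  d <- make_trial_mediation_data(100, a = 2, b = 0.5, seed = 32)
  out <- impute_missing(d, n_imputations = 3, seed = 1)
  expect_length(out, 3)
  for (m in out) expect_identical(m, d)

  d2 <- d
  set.seed(33)
  d2$mediator[sample(100, 20)] <- NA
  out2 <- impute_missing(d2, n_imputations = 3, seed = 1)
  for (m in out2) {
    expect_false(anyNA(m))
    expect_identical(m$outcome, d2$outcome)  # fully observed column unchanged
    expect_identical(m$arm, d2$arm)
  }
  # observed mediator cells are untouched
  obs <- !is.na(d2$mediator)
  expect_identical(out2[[1]]$mediator[obs], d2$mediator[obs])

  d3 <- d; d3$mediator[1:95] <- NA
  expect_error(impute_missing(d3), ">90%")
})

test_that("imputed values recover a planted mean under MCAR", {
  set.seed(34)
  n <- 2000
  d <- data.frame(w = rnorm(n), v = NA_real_)
  d$v <- 30 + 0.5 * d$w + rnorm(n)
  sd_v <- sd(d$v)
  d$v[sample(n, n * 0.2)] <- NA
  out <- impute_missing(d, n_imputations = 5, seed = 2)
  pooled <- mean(sapply(out, function(m) mean(m$v)))
  expect_lt(abs(pooled - 30), 3 * sd_v / sqrt(n))
})

test_that("counterfactual effects decompose additively and match path products", {
  d <- make_trial_mediation_data(800, a = 2, b = -0.5, direct = -1, seed = 35)
  spec <- counterfactual_spec(exposure = "arm", mediator = "mediator",
                              outcome = "outcome",
                              baseline_covariates = "age",
                              scale_outcome = FALSE, mediator_draws = 0)
  eff <- counterfactual_effects(d, spec)
  expect_equal(eff$te, eff$nde + eff$nie, tolerance = 1e-8)
  # linear no-interaction: nie equals the product of the fitted a and b paths
  paths <- fit_mediation_paths(d$arm, d$mediator, d$outcome,
                               covariates = d["age"])
  expect_equal(eff$nie, paths$ab, tolerance = 1e-8)
  # and is close to the planted product
  se_ab <- sqrt(paths$b^2 * paths$se_a^2 + paths$a^2 * paths$se_b^2)
  expect_lt(abs(eff$nie - 2 * (-0.5)), 3 * se_ab)
})

test_that("zero mediator path collapses the indirect effect", {
  set.seed(36)
  n <- 1500
  d <- make_trial_mediation_data(n, a = 2, b = 0, direct = -1, seed = 36)
  spec <- counterfactual_spec(exposure = "arm", mediator = "mediator",
                              outcome = "outcome", baseline_covariates = "age",
                              scale_outcome = FALSE, mediator_draws = 0)
  eff <- counterfactual_effects(d, spec)
  expect_lt(abs(eff$nie), 0.15)
  expect_equal(eff$te, eff$nde, tolerance = 0.15)
})

test_that("decomposition variants coincide without interaction, stochastic draws agree", {
  d <- make_trial_mediation_data(400, a = 1.5, b = -0.4, direct = -0.5, seed = 37)
  base <- list(exposure = "arm", mediator = "mediator", outcome = "outcome",
               baseline_covariates = "age", scale_outcome = FALSE)
  s_pure <- do.call(counterfactual_spec, c(base, mediator_draws = 0,
                                           decomposition = "pure_nie_total_nde"))
  s_total <- do.call(counterfactual_spec, c(base, mediator_draws = 0,
                                            decomposition = "total_nie_pure_nde"))
  e1 <- counterfactual_effects(d, s_pure)
  e2 <- counterfactual_effects(d, s_total)
  expect_equal(e1$nie, e2$nie, tolerance = 1e-10)
  expect_equal(e1$nde, e2$nde, tolerance = 1e-10)
  # stochastic mediator simulation agrees with the plug-in in the linear case
  s_mc <- do.call(counterfactual_spec, c(base, mediator_draws = 200))
  set.seed(38)
  e3 <- counterfactual_effects(d, s_mc)
  expect_equal(e3$nie, e1$nie, tolerance = 1e-8)  # linear in M: exact
  expect_equal(e3$te, e1$te, tolerance = 1e-8)
  # with interaction the decomposition still telescopes
  s_int <- do.call(counterfactual_spec, c(base, mediator_draws = 50,
                                          interaction = TRUE))
  set.seed(39)
  e4 <- counterfactual_effects(d, s_int)
  expect_equal(e4$te, e4$nde + e4$nie, tolerance = 1e-8)
})

test_that("swapping arm labels negates the effects and preserves pm", {
  d <- make_trial_mediation_data(400, a = 1.5, b = -0.5, direct = -1, seed = 40)
  spec <- counterfactual_spec(exposure = "arm", mediator = "mediator",
                              outcome = "outcome", baseline_covariates = "age",
                              scale_outcome = FALSE, mediator_draws = 0)
  e1 <- counterfactual_effects(d, spec)
  d2 <- d; d2$arm <- 1 - d2$arm
  e2 <- counterfactual_effects(d2, spec)
  expect_equal(e2$te, -e1$te, tolerance = 1e-8)
  expect_equal(e2$nde, -e1$nde, tolerance = 1e-8)
  expect_equal(e2$nie, -e1$nie, tolerance = 1e-8)
  expect_equal(e2$pm, e1$pm, tolerance = 1e-8)
})

test_that("pooled analysis is seed-deterministic and degenerates correctly", {
  d <- make_trial_mediation_data(200, a = 2, b = -0.5, direct = -1, seed = 41)
  spec <- counterfactual_spec(exposure = "arm", mediator = "mediator",
                              outcome = "outcome", baseline_covariates = "age",
                              scale_outcome = FALSE, mediator_draws = 0,
                              n_imputations = 3, n_boot = 60, seed = 7)
  r1 <- pool_and_ci(spec, d)
  r2 <- pool_and_ci(spec, d)
  expect_identical(r1[c("te", "nde", "nie", "pm", "ci", "p")],
                   r2[c("te", "nde", "nie", "pm", "ci", "p")])
  # no missingness: pooled point estimate equals the single-dataset estimate
  single <- counterfactual_effects(d, spec)
  expect_equal(r1$te, single$te, tolerance = 1e-10)
  expect_equal(r1$nie, single$nie, tolerance = 1e-10)
  expect_true(r1$ci$nie[1] <= r1$nie && r1$nie <= r1$ci$nie[2])
})

test_that("null trials yield indirect-effect intervals that cover zero", {
  spec <- counterfactual_spec(exposure = "arm", mediator = "mediator",
                              outcome = "outcome", baseline_covariates = "age",
                              scale_outcome = FALSE, mediator_draws = 0,
                              n_imputations = 2, n_boot = 150, seed = 5)
  covered <- sapply(1:25, function(i) {
    d <- make_trial_mediation_data(150, a = 0, b = 0.4, direct = 0,
                                   seed = 500 + i)
    set.seed(i)
    d$mediator[runif(150) < 0.1] <- NA  # a little missingness to exercise MI
    r <- pool_and_ci(spec, d)
    r$ci$nie[1] <= 0 && 0 <= r$ci$nie[2]
  })
  expect_gte(mean(covered), 0.84)
})
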