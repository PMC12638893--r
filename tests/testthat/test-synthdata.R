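test_that("generators are fully deterministic under a seed", {
  o1 <- generate_observational(observational_config(n_participants = 40,
                                                    seed = 49))
  o2 <- generate_observational(observational_config(n_participants = 40,
                                                    seed = 49))
  expect_identical(o1$monitoring, o2$monitoring)
  expect_identical(o1$battery, o2$battery)
  o3 <- generate_observational(observational_config(n_participants = 40,
                                                    seed = 50))
  expect_false(identical(o1$monitoring, o3$monitoring))

  r1 <- generate_rct(rct_config(n_per_arm = 20, seed = 51))
  r2 <- generate_rct(rct_config(n_per_arm = 20, seed = 51))
  expect_identical(r1$long, r2$long)
  expect_identical(r1$wide, r2$wide)
})

test_that("stressor draws match their configured rates", {
  cfg <- observational_config(n_participants = 800, n_timepoints = 13,
                              sd_exposure_propensity = 0,  # clean margins
                              missing_rate = 0, seed = 52)
  obs <- generate_observational(cfg)
  nr <- nrow(obs$monitoring)
  for (j in c(1, 5, 15)) {
    lambda <- cfg$le_rates[j]
    mean_j <- mean(obs$monitoring[[paste0("le_", j)]])
    expect_lt(abs(mean_j - lambda), 3 * sqrt(lambda / nr))
  }
  for (j in c(1, 20, 58)) {
    mu <- 7 * cfg$dh_probs[j]
    mean_j <- mean(obs$monitoring[[paste0("dh_", j)]])
    se <- sqrt(7 * cfg$dh_probs[j] * (1 - cfg$dh_probs[j]) / nr)
    expect_lt(abs(mean_j - mu), 3 * se)
  }
})

test_that("a null configuration produces flat symptoms and near-zero SR", {
  cfg <- observational_config(n_participants = 60, slope_EP = 0,
                              sd_resid_P = 0, sd_reactivity = 0,
                              a1 = 0, a2 = 0, g1 = 0, g2 = 0,
                              missing_rate = 0, seed = 53)
  obs <- generate_observational(cfg)
  expect_equal(stats::sd(obs$monitoring$P), 0)
  e <- freshmo_exposure(obs$monitoring)
  expect_gt(stats::sd(e$E), 0)  # exposure still varies via stressor draws
  mon <- merge(e[c("participant_id", "time_index", "E")],
               obs$monitoring[c("participant_id", "time_index", "P")],
               by = c("participant_id", "time_index"))
  model <- suppressWarnings(fit_normative_ols(
    tapply(mon$E, mon$participant_id, mean),
    tapply(mon$P, mon$participant_id, mean)))
  sr <- compute_interval_sr(model, mon, 1:12, min_monitorings = 2)
  expect_lt(max(abs(sr$sr)), 1e-8)
})

test_that("planted reactivity offsets dominate estimated SR ranks", {
  # residual SD set to half the reactivity SD
  cfg <- observational_config(n_participants = 500, sd_reactivity = 4,
                              sd_resid_P = 2, missing_rate = 0, seed = 54)
  obs <- generate_observational(cfg)
  e <- freshmo_exposure(obs$monitoring)
  mon <- merge(e[c("participant_id", "time_index", "E")],
               obs$monitoring[c("participant_id", "time_index", "P")],
               by = c("participant_id", "time_index"))
  est <- mon[mon$time_index %in% 1:3, ]
  agg <- aggregate(cbind(E, P) ~ participant_id, data = est, FUN = mean)
  model <- fit_normative_ols(agg$E, agg$P)
  sr <- compute_interval_sr(model, mon, 1:12, min_monitorings = 4)
  truth <- obs$truth$reactivity[match(sr$participant_id,
                                      sprintf("p%04d", seq_len(500)))]
  expect_gt(cor(truth, sr$sr, method = "spearman"), 0.8)
})

test_that("trial generator honors allocation, trajectories and planted effects", {
  rct <- generate_rct(rct_config(n_per_arm = 60, seed = 55))
  expect_equal(sum(rct$wide$arm == 0), 60)
  expect_equal(sum(rct$wide$arm == 1), 60)
  expect_equal(rct$truth$pm, 0.4, tolerance = 1e-12)
  # control PAS flat, intervention rising by pas_gain per step (in truth)
  pas <- rct$truth$pas_full
  ctrl <- rct$wide$arm == 0
  drift_ctrl <- mean(pas[ctrl, 4] - pas[ctrl, 1])
  drift_int <- mean(pas[!ctrl, 4] - pas[!ctrl, 1])
  expect_lt(abs(drift_ctrl), 1)
  expect_equal(drift_int, 3 * rct$config$pas_gain, tolerance = 1)

  # null trial: no interaction signal, no indirect effect
  null <- generate_rct(rct_config(n_per_arm = 100, pas_gain = 0,
                                  direct_gain = 0, seed = 56))
  fit <- fit_group_time(null$long[null$long$outcome_name == "SR", ])
  row <- fit$fixed[fit$fixed$term == "arm:time", ]
  expect_true(row$ci_low <= 0 && 0 <= row$ci_high)
  spec <- counterfactual_spec(mediator_draws = 0)
  eff <- counterfactual_effects(null$wide[complete.cases(null$wide), ], spec)
  expect_lt(abs(eff$nie), 2)  # 0-100 outcome scale
})

test_that("missingness injection is MCAR at the requested rate and seeded", {
  d <- data.frame(participant_id = sprintf("p%05d", 1:5000),
                  a = rnorm(5000), b = rnorm(5000))
  expect_identical(inject_missingness(d, 0), d)
  m1 <- inject_missingness(d, 0.2, seed = 57)
  m2 <- inject_missingness(d, 0.2, seed = 57)
  expect_identical(m1, m2)
  frac <- mean(is.na(as.matrix(m1[c("a", "b")])))
  expect_gt(frac, 0.18); expect_lt(frac, 0.22)
  expect_false(anyNA(m1$participant_id))
  expect_error(inject_missingness(d, 1), "rate")
})
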