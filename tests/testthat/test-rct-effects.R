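# build a balanced long table for one outcome under a linear cell-mean model
make_long_outcome <- function(n_per_arm, times = 0:3, g = 0, t = 0, i = 0,
                              sd = 1, seed = 1, covariate_effect = 0) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- rep(c(0, 1), each = n_per_arm)
  age <- rnorm(n, 40, 8)
  d <- expand.grid(idx = seq_len(n), time = times)
  d$participant_id <- sprintf("p%03d", d$idx)
  d$arm <- arm[d$idx]
  d$age <- age[d$idx]
  d$gender <- rbinom(n, 1, 0.5)[d$idx]
  d$education <- sample(0:2, n, replace = TRUE)[d$idx]
  d$value <- 10 + g * d$arm + t * d$time + i * d$arm * d$time +
    covariate_effect * d$age + rnorm(nrow(d), sd = sd)
  d
}

test_that("group-time model recovers a saturated linear cell structure", {
  d <- make_long_outcome(30, g = 2, t = -1, i = 0.5, sd = 0.001, seed = 42)
  fit <- fit_group_time(d, covariates = character(0))
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["arm"]), 2, tolerance = 0.01)
  expect_equal(unname(est["time"]), -1, tolerance = 0.01)
  expect_equal(unname(est["arm:time"]), 0.5, tolerance = 0.01)
})

test_that("group-time model recovers a planted interaction within 3 SEs", {
  d <- make_long_outcome(100, g = 0.5, t = -0.5, i = -1, sd = 2, seed = 43)
  fit <- fit_group_time(d)
  row <- fit$fixed[fit$fixed$term == "arm:time", ]
  se <- (row$ci_high - row$ci_low) / (2 * 1.96)
  expect_lt(abs(row$estimate - (-1)), 3 * se)
  expect_lt(row$p, 0.05)
})

test_that("group-label swap negates the group and interaction coefficients", {
  d <- make_long_outcome(40, g = 1, t = 0.3, i = -0.6, sd = 1, seed = 44)
  f1 <- fit_group_time(d, covariates = character(0))
  d2 <- d; d2$arm <- 1 - d2$arm
  f2 <- fit_group_time(d2, covariates = character(0))
  e1 <- setNames(f1$fixed$estimate, f1$fixed$term)
  e2 <- setNames(f2$fixed$estimate, f2$fixed$term)
  expect_equal(unname(e2["arm:time"]), -unname(e1["arm:time"]), tolerance = 1e-6)
  expect_equal(unname(e2["time"]), unname(e1["time"] + e1["arm:time"]),
               tolerance = 1e-6)
})

test_that("interaction CIs attain near-nominal coverage on model-generated data", {
  hits <- sapply(1:100, function(r) {
    d <- make_long_outcome(25, g = 0.5, t = -0.5, i = -1, sd = 2,
                           seed = 4000 + r)
    fit <- fit_group_time(d, covariates = character(0))
    row <- fit$fixed[fit$fixed$term == "arm:time", ]
    row$ci_low <= -1 && -1 <= row$ci_high
  })
  expect_gte(mean(hits), 0.88)
})

test_that("estimated marginal means reduce to cell means on balanced data", {
  d <- make_long_outcome(30, g = 1.5, t = -0.8, i = 0.4, sd = 1, seed = 45)
  fit <- fit_group_time(d, covariates = character(0))
  emm <- estimated_marginal_means(fit)
  expect_equal(nrow(emm), 8)  # 2 arms x 4 times, all observed
  cells <- aggregate(value ~ arm + time, data = d, FUN = mean)
  m <- merge(emm, cells, by = c("arm", "time"))
  # linear-in-time model smooths the raw means; agreement within noise
  expect_lt(max(abs(m$emmean - m$value)), 0.5)
  expect_true(all(m$ci_low < m$emmean & m$emmean < m$ci_high))
  expect_true(all(m$n == 30))
})

test_that("EMMs with a covariate equal manual predictions at the covariate mean", {
  d <- make_long_outcome(40, g = 1, t = -0.5, i = 0.3, sd = 1, seed = 46,
                         covariate_effect = 1.0)
  fit <- fit_group_time(d, covariates = "age")
  emm <- estimated_marginal_means(fit)
  b <- lme4::fixef(fit$fit)
  manual <- function(a, t) unname(b["(Intercept)"] + b["arm"] * a +
                                    b["time"] * t + b["age"] * mean(d$age) +
                                    b["arm:time"] * a * t)
  for (k in seq_len(nrow(emm)))
    expect_equal(emm$emmean[k], manual(emm$arm[k], emm$time[k]),
                 tolerance = 1e-6)
})

test_that("baseline-PAS model recovers planted coefficients and handles shifts", {
  rct <- generate_rct(rct_config(n_per_arm = 150, b_pas_sr = -0.03,
                                 pas_gain = 0, direct_gain = 0, seed = 47))
  srl <- rct$long[rct$long$outcome_name == "SR" & rct$long$time >= 1, ]
  srl$sr <- srl$value
  srl$pas_t0 <- rct$wide$pas_t0[match(srl$participant_id,
                                      rct$wide$participant_id)]
  suppressMessages(fit <- fit_baseline_pas_prediction(srl))
  se <- (fit$ci_high - fit$ci_low) / (2 * 1.96)
  expect_lt(abs(fit$estimate - (-0.03)), 3 * se)

  # permuted baseline PAS carries no signal
  set.seed(48)
  srl2 <- srl
  perm <- sample(unique(srl2$participant_id))
  names(perm) <- unique(srl2$participant_id)
  srl2$pas_t0 <- rct$wide$pas_t0[match(perm[srl2$participant_id],
                                       rct$wide$participant_id)]
  suppressMessages(fit2 <- fit_baseline_pas_prediction(srl2))
  se2 <- (fit2$ci_high - fit2$ci_low) / (2 * 1.96)
  expect_lt(abs(fit2$estimate), 3 * se2)

  # adding a constant to SR changes only the intercept
  srl3 <- srl; srl3$sr <- srl3$sr + 50
  suppressMessages(fit3 <- fit_baseline_pas_prediction(srl3))
  expect_equal(fit3$estimate, fit$estimate, tolerance = 1e-5)
  i1 <- fit$fixed$estimate[fit$fixed$term == "(Intercept)"]
  i3 <- fit3$fixed$estimate[fit3$fixed$term == "(Intercept)"]
  expect_equal(i3 - i1, 50, tolerance = 1e-4)
})
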