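test_that("baseline OLS normative line handles exact and noisy data", {
  E <- c(-1, 0, 1, 2, 3)
  flat <- suppressWarnings(fit_normative_ols(E, rep(20, 5)))
  expect_equal(flat$b1, 0, tolerance = 1e-12)
  expect_equal(flat$b0, 20, tolerance = 1e-12)

  line <- suppressWarnings(fit_normative_ols(E, 2 + 0.5 * E))
  expect_equal(line$b0, 2, tolerance = 1e-10)
  expect_equal(line$b1, 0.5, tolerance = 1e-10)
  expect_equal(line$r2, 1, tolerance = 1e-10)

  set.seed(8)
  En <- rnorm(5000); Pn <- 2 + 0.5 * En + rnorm(5000)
  noisy <- fit_normative_ols(En, Pn)
  se <- summary(noisy$fit)$coefficients["E", 2]
  expect_lt(abs(noisy$b1 - 0.5), 3 * se)
  # estimation residuals average to zero
  expect_lt(abs(mean(residuals(noisy$fit))), 1e-8)

  expect_error(fit_normative_ols(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(fit_normative_ols(1:2, 1:2), "at least 3")
})

test_that("quadratic lack-of-fit test behaves at both extremes", {
  E <- seq(-2, 2, length.out = 50)
  lin <- quadratic_check(E, 1 + 2 * E)
  expect_equal(lin$df, 1L)
  # exact-fit likelihoods are numerically delicate; the statistic stays far
  # below any chi-square(1) critical value
  expect_lt(lin$statistic, 0.5)
  expect_gt(lin$p, 0.4)

  set.seed(9)
  En <- rnorm(1000); Pn <- En^2 + rnorm(1000, sd = 0.5)
  curved <- quadratic_check(En, Pn)
  expect_lt(curved$p, 0.001)
  expect_equal(curved$df, 1L)
})

test_that("interval SR scores are residuals to the line with the stated filters", {
  model <- suppressWarnings(
    fit_normative_ols(c(0, 1, 2, 3), c(10, 12, 14, 16)))  # P = 10 + 2E
  # participant on the line -> SR = 0; one above by +3
  mon <- make_monitoring(rep(c("a", "b"), each = 3), rep(1:3, 2),
                         E = c(1, 1, 1, 2, 2, 2),
                         P = c(12, 12, 12, 17, 17, 17))
  sr <- compute_interval_sr(model, mon, interval = 1:3, min_monitorings = 2)
  expect_equal(sr$sr[sr$participant_id == "a"], 0, tolerance = 1e-12)
  expect_equal(sr$sr[sr$participant_id == "b"], 3, tolerance = 1e-12)

  # monitoring-count filter: counts {4,3,2,5,1} with minimum 4 keeps 2
  counts <- c(4, 3, 2, 5, 1)
  mon2 <- do.call(rbind, lapply(seq_along(counts), function(i)
    make_monitoring(sprintf("p%d", i), seq_len(counts[i]),
                    E = rnorm(counts[i]), P = rnorm(counts[i]))))
  sr2 <- compute_interval_sr(model, mon2, interval = 1:5, min_monitorings = 4)
  expect_equal(nrow(sr2), 2L)
  expect_setequal(sr2$participant_id, c("p1", "p4"))
  expect_equal(sort(sr2$n_monitorings_used), c(4L, 5L))
})

test_that("SR shifts with P under a fixed model but not under refitting", {
  set.seed(10)
  n <- 40
  E <- rnorm(n); P <- 5 + 2 * E + rnorm(n)
  mon <- make_monitoring(sprintf("p%02d", 1:n), 1, E, P)
  model <- fit_normative_ols(E, P)
  sr0 <- compute_interval_sr(model, mon, 1, min_monitorings = 1)
  monc <- mon; monc$P <- monc$P + 7
  src_fixed <- compute_interval_sr(model, monc, 1, min_monitorings = 1)
  expect_equal(src_fixed$sr, sr0$sr + 7, tolerance = 1e-10)
  refit <- fit_normative_ols(monc$E, monc$P)
  src_refit <- compute_interval_sr(refit, monc, 1, min_monitorings = 1)
  expect_equal(src_refit$sr, sr0$sr, tolerance = 1e-10)
})

test_that("interval SR ignores row order and duplicated-then-deduplicated rows", {
  set.seed(12)
  mon <- make_monitoring(rep(sprintf("p%d", 1:6), each = 4), rep(1:4, 6),
                         E = rnorm(24), P = rnorm(24, 15))
  model <- fit_normative_ols(rnorm(10), rnorm(10, 15))
  sr <- compute_interval_sr(model, mon, 1:4, min_monitorings = 2)
  shuffled <- mon[sample(nrow(mon)), ]
  sr_sh <- compute_interval_sr(model, shuffled, 1:4, min_monitorings = 2)
  expect_equal(sr_sh[order(sr_sh$participant_id), ],
               sr[order(sr$participant_id), ], ignore_attr = TRUE)
  dup <- rbind(mon, mon[1:5, ])
  sr_dup <- compute_interval_sr(model, dup, 1:4, min_monitorings = 2)
  expect_equal(sr_dup[order(sr_dup$participant_id), ],
               sr[order(sr$participant_id), ], ignore_attr = TRUE)
})

test_that("mixed normative model degenerates to OLS without heterogeneity", {
  set.seed(13)
  n <- 150; tpts <- 4
  d <- make_monitoring(rep(sprintf("p%03d", 1:n), each = tpts),
                       rep(1:tpts, n), E = rnorm(n * tpts), P = NA)
  d$P <- 3 + 1.5 * d$E + rnorm(nrow(d))
  suppressMessages(m <- fit_normative_lmm(d))
  ols <- lm(P ~ E, data = d)
  expect_lt(m$var_random, 0.15)
  expect_equal(m$b0, unname(coef(ols)[1]), tolerance = 0.05)
  expect_equal(m$b1, unname(coef(ols)[2]), tolerance = 0.05)
  # residual definition: P = fixed prediction + SR, row by row
  expect_equal(d$P[1:10], m$b0 + m$b1 * d$E[1:10] + m$sr$sr[1:10],
               tolerance = 1e-10)
})

test_that("mixed normative model recovers a planted random-intercept SD", {
  set.seed(14)
  n <- 500; tpts <- 4
  u <- rnorm(n, sd = 3)
  d <- make_monitoring(rep(sprintf("p%03d", 1:n), each = tpts),
                       rep(1:tpts, n), E = rnorm(n * tpts), P = NA)
  d$P <- 10 + 2 * d$E + u[as.integer(factor(d$participant_id))] + rnorm(nrow(d))
  suppressMessages(m <- fit_normative_lmm(d))
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  sd_int <- vc$sdcor[vc$grp == "participant_id" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  expect_lt(abs(sd_int - 3) / 3, 0.15)
  expect_true(m$r2_marginal <= m$r2_conditional)
  expect_true(m$r2_conditional <= 1)
})

test_that("variance decomposition follows the component formulas", {
  fake <- structure(list(kind = "lmm_random_slope", var_fixed = 4,
                         var_random = 2, var_resid = 2),
                    class = "normative_model")
  r2 <- variance_explained(fake)
  expect_equal(r2$r2_marginal, 0.5)
  expect_equal(r2$r2_conditional, 0.75)
  limit <- structure(list(kind = "lmm_random_slope", var_fixed = 4,
                          var_random = 0, var_resid = 0),
                     class = "normative_model")
  expect_equal(variance_explained(limit)$r2_conditional, 1)
  degen <- structure(list(kind = "lmm_random_slope", var_fixed = 0,
                          var_random = 0, var_resid = 0),
                     class = "normative_model")
  expect_error(variance_explained(degen), "zero")
  expect_error(variance_explained(fit_normative_ols(1:5, c(2, 3, 5, 7, 8))),
               "mixed-model")
})
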