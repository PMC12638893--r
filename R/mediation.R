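#' Linear-regression mediation path estimates
#'
#' Classic product-of-coefficients setup on complete cases:
#' `a` from M ~ X (+ covariates), `b` and `c'` from Y ~ X + M (+ covariates),
#' `c` from Y ~ X (+ covariates). With identical covariate sets the OLS
#' identity `c = c' + a * b` holds exactly.
#'
#' @param x,m,y Numeric vectors: predictor, mediator, outcome.
#' @param covariates Optional data frame / matrix of covariates.
#' @return List of class `mediation_paths`: `a`, `b`, `c`, `c_prime`, each
#'   with standard errors (`se_a` etc.), `ab` (= a*b), and `n`.
#' @export
fit_mediation_paths <- function(x, m, y, covariates = NULL) {
  d <- data.frame(x = x, m = m, y = y)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  covs <- setdiff(names(d), c("x", "m", "y"))
  if (nrow(d) <= length(covs) + 3) stop("too few complete cases")
  f_m <- stats::reformulate(c("x", covs), response = "m")
  f_y <- stats::reformulate(c("x", "m", covs), response = "y")
  f_c <- stats::reformulate(c("x", covs), response = "y")
  fm <- stats::lm(f_m, data = d)
  fy <- stats::lm(f_y, data = d)
  fc <- stats::lm(f_c, data = d)
  if (anyNA(stats::coef(fm)) || anyNA(stats::coef(fy)))
    stop("collinear design in mediation models")
  sm <- summary(fm)$coefficients; sy <- summary(fy)$coefficients
  sc <- summary(fc)$coefficients
  structure(list(a = sm["x", 1], se_a = sm["x", 2],
                 b = sy["m", 1], se_b = sy["m", 2],
                 c_prime = sy["x", 1], se_c_prime = sy["x", 2],
                 c = sc["x", 1], se_c = sc["x", 2],
                 ab = sm["x", 1] * sy["m", 1],
                 n = nrow(d)),
            class = "mediation_paths")
}

#' Bootstrap inference for the indirect effect a*b
#'
#' Nonparametric case-resampling bootstrap: rows (cases) are resampled with
#' replacement, the path models are refitted, and the indirect effect a*b is
#' recorded per resample. The reported indirect effect is the mean over
#' resamples with a percentile confidence interval; it is called significant
#' when the interval excludes zero. Fully determined by (data, seed).
#'
#' @inheritParams fit_mediation_paths
#' @param n_boot Number of resamples (default 5000).
#' @param seed Integer RNG seed.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `mediation_result`: the point-estimate paths, and
#'   `ab_mean`, `ab_ci` (length-2), `significant`, `n_boot`, `seed`,
#'   `ab_boot` (the resample draws).
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, n_boot = 5000,
                               seed = 1L, conf_level = 0.95) {
  paths <- fit_mediation_paths(x, m, y, covariates)
  d <- data.frame(x = x, m = m, y = y)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  covs <- setdiff(names(d), c("x", "m", "y"))
  Xm <- as.matrix(cbind(1, d$x, d[covs]))
  Xy <- as.matrix(cbind(1, d$x, d$m, d[covs]))
  n <- nrow(d)
  set.seed(seed)
  ab <- numeric(n_boot)
  i <- 1L
  while (i <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(d$x[idx]) == 0 || stats::sd(d$m[idx]) == 0) next  # degenerate: redraw
    a_hat <- tryCatch(stats::lm.fit(Xm[idx, , drop = FALSE], d$m[idx])$coefficients[2],
                      error = function(e) NA_real_)
    b_hat <- tryCatch(stats::lm.fit(Xy[idx, , drop = FALSE], d$y[idx])$coefficients[3],
                      error = function(e) NA_real_)
    if (is.na(a_hat) || is.na(b_hat)) next
    ab[i] <- a_hat * b_hat
    i <- i + 1L
  }
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(ab, c(alpha, 1 - alpha)))
  structure(c(unclass(paths),
              list(ab_mean = mean(ab), ab_ci = ci,
                   significant = ci[1] > 0 || ci[2] < 0,
                   n_boot = n_boot, seed = seed, ab_boot = ab)),
            class = c("mediation_result", "mediation_paths"))
}

#' Monte-Carlo power analysis for an indirect effect
#'
#' Power for detecting a nonzero indirect effect a*b at a given sample size,
#' in the style of Schoemann, Boulton & Short (2017): per repetition a
#' trivariate dataset of size `n` is simulated from the standardized path
#' model `M = a X + e_m`, `Y = c' X + b M + e_y`; the paths are estimated; a
#' Monte-Carlo confidence interval for a*b is formed by drawing
#' `mc_draws` pairs (a*, b*) from the estimated sampling distributions and
#' taking percentiles of the products; the repetition counts as significant
#' when that interval excludes zero.
#'
#' @param a,b Path coefficients X->M and M->Y.
#' @param c_prime Direct X->Y path (default 0).
#' @param n Sample size per repetition (ignored when `target_power` is given
#'   and a search is requested).
#' @param reps Repetitions (default 1000).
#' @param mc_draws Monte-Carlo draws per repetition (default 20000).
#' @param seed Integer RNG seed.
#' @param sd_x,sd_em,sd_ey Standard deviations of X and the two residuals
#'   (default 1: standardized-path metric).
#' @param conf_level Confidence level of the Monte-Carlo interval.
#' @param target_power If non-`NULL`, search the grid `n_grid` (steps of 10)
#'   for the smallest n whose power meets the target; `power` and `n` then
#'   refer to that n.
#' @param n_grid Candidate sample sizes for the search.
#' @return List of class `power_result`: `power`, `n`, `reps`, `mc_draws`,
#'   `seed`, and `n_for_target`/`target_power`/`power_grid` when a search ran.
#' @export
monte_carlo_power <- function(a, b, c_prime = 0, n, reps = 1000,
                              mc_draws = 20000, seed = 1L,
                              sd_x = 1, sd_em = 1, sd_ey = 1,
                              conf_level = 0.95,
                              target_power = NULL,
                              n_grid = seq(50, 1000, by = 10)) {
  set.seed(seed)
  one_n <- function(n) {
    alpha <- (1 - conf_level) / 2
    hits <- 0L
    for (r in seq_len(reps)) {
      X <- stats::rnorm(n, sd = sd_x)
      M <- a * X + stats::rnorm(n, sd = sd_em)
      Y <- c_prime * X + b * M + stats::rnorm(n, sd = sd_ey)
      fm <- stats::lm(M ~ X)
      fy <- stats::lm(Y ~ X + M)
      sa <- summary(fm)$coefficients["X", ]
      sb <- summary(fy)$coefficients["M", ]
      a_mc <- stats::rnorm(mc_draws, sa[1], sa[2])
      b_mc <- stats::rnorm(mc_draws, sb[1], sb[2])
      ci <- stats::quantile(a_mc * b_mc, c(alpha, 1 - alpha), names = FALSE)
      if (ci[1] > 0 || ci[2] < 0) hits <- hits + 1L
    }
    hits / reps
  }
  if (is.null(target_power)) {
    res <- list(power = one_n(n), n = as.integer(n), reps = as.integer(reps),
                mc_draws = as.integer(mc_draws), seed = as.integer(seed))
  } else {
    grid_power <- c()
    n_for_target <- NA_integer_
    for (nn in n_grid) {
      p <- one_n(nn)
      grid_power[as.character(nn)] <- p
      if (p >= target_power) { n_for_target <- as.integer(nn); break }
    }
    res <- list(power = unname(utils::tail(grid_power, 1)),
                n = n_for_target, reps = as.integer(reps),
                mc_draws = as.integer(mc_draws), seed = as.integer(seed),
                n_for_target = n_for_target, target_power = target_power,
                power_grid = grid_power)
  }
  structure(res, class = "power_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n", x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("c = %.3f, c' = %.3f\n", x$c, x$c_prime))
  cat(sprintf("indirect ab = %.3f, bootstrap mean %.3f, 95%% CI [%.3f, %.3f] (%d resamples)\n",
              x$ab, x$ab_mean, x$ab_ci[1], x$ab_ci[2], x$n_boot))
  invisible(x)
}

#' @export
print.power_result <- function(x, ...) {
  if (!is.null(x$n_for_target) && !is.na(x$n_for_target))
    cat(sprintf("smallest n with power >= %.2f: %d (power %.3f)\n",
                x$target_power, x$n_for_target, x$power))
  else
    cat(sprintf("power = %.3f at n = %d (%d reps, %d MC draws)\n",
                x$power, x$n, x$reps, x$mc_draws))
  invisible(x)
}
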