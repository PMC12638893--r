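#' Specification for counterfactual (natural-effects) mediation
#'
#' Describes a two-arm trial mediation problem: binary arm indicator,
#' mediator measured post-intervention but before the outcome, outcome on an
#' additive scale, and baseline covariates. By default the pure natural
#' indirect effect and the total natural direct effect are reported — the
#' pairing in which the direct effect absorbs any exposure-mediator
#' interaction.
#'
#' @param exposure,mediator,outcome Column names in the analysis data.
#' @param baseline_covariates Character vector of baseline covariate columns.
#' @param interaction Include an exposure x mediator term in the outcome
#'   model?
#' @param decomposition `"pure_nie_total_nde"` (default) or
#'   `"total_nie_pure_nde"`.
#' @param scale_outcome Min-max scale the outcome to 0-100 before estimation
#'   (constants frozen from the analysis sample)?
#' @param mediator_draws Number of stochastic draws from the fitted mediator
#'   model per subject when simulating counterfactual mediator values
#'   (normal errors). `0` uses the deterministic model-mean plug-in, which is
#'   exact in expectation for linear outcome models.
#' @param n_imputations Number of imputed datasets for missing data.
#' @param n_boot Bootstrap resamples for interval estimation.
#' @param seed Integer RNG seed.
#' @return List of class `counterfactual_spec`.
#' @export
counterfactual_spec <- function(exposure = "arm", mediator = "pas_t2",
                                outcome = "sr_t3",
                                baseline_covariates = c("age", "gender",
                                                        "education", "pas_t0",
                                                        "sr_t0"),
                                interaction = FALSE,
                                decomposition = c("pure_nie_total_nde",
                                                  "total_nie_pure_nde"),
                                scale_outcome = TRUE,
                                mediator_draws = 100L,
                                n_imputations = 5L, n_boot = 1000L,
                                seed = 1L) {
  decomposition <- match.arg(decomposition)
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 baseline_covariates = baseline_covariates,
                 interaction = isTRUE(interaction),
                 decomposition = decomposition,
                 scale_outcome = isTRUE(scale_outcome),
                 mediator_draws = as.integer(mediator_draws),
                 n_imputations = as.integer(n_imputations),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "counterfactual_spec")
}

#' Chained-equation multiple imputation with normal linear models
#'
#' Produces `n_imputations` completed copies of the dataset. Missing cells
#' are initialized at observed-column means, then each incomplete column is
#' repeatedly (10 sweeps) re-imputed by stochastic regression on all other
#' columns: a linear model is fitted to the currently observed/imputed values
#' and missing entries are replaced by prediction plus a normal residual
#' draw. Fully observed columns are returned unchanged.
#'
#' @param dataset Data frame; only numeric columns are imputed.
#' @param n_imputations Number of completed datasets (default 5).
#' @param seed Integer RNG seed.
#' @param exclude Columns never used as predictors nor imputed (ids).
#' @param sweeps Chained-equation sweeps per imputation.
#' @return List of `n_imputations` completed data frames.
#' @export
impute_missing <- function(dataset, n_imputations = 5L, seed = 1L,
                           exclude = "participant_id", sweeps = 10L) {
  stopifnot(is.data.frame(dataset))
  num_cols <- setdiff(names(dataset)[vapply(dataset, is.numeric, logical(1))],
                      exclude)
  miss_frac <- vapply(dataset[num_cols], function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac > 0.9))
    stop("column(s) with >90% missing: ",
         paste(num_cols[miss_frac > 0.9], collapse = ", "))
  incomplete <- num_cols[miss_frac > 0]
  if (!length(incomplete))
    return(replicate(n_imputations, dataset, simplify = FALSE))
  set.seed(seed)
  lapply(seq_len(n_imputations), function(it) {
    d <- dataset
    # mean initialization
    for (v in incomplete)
      d[[v]][is.na(d[[v]])] <- mean(dataset[[v]], na.rm = TRUE)
    for (s in seq_len(sweeps)) {
      for (v in sample(incomplete)) {
        obs <- !is.na(dataset[[v]])
        preds <- setdiff(num_cols, v)
        preds <- preds[vapply(d[preds], function(x) stats::sd(x) > 0, logical(1))]
        X <- as.matrix(cbind(1, d[preds]))
        fit <- stats::lm.fit(X[obs, , drop = FALSE], dataset[[v]][obs])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        dfres <- max(sum(obs) - sum(!is.na(fit$coefficients)), 1)
        sigma <- sqrt(sum(fit$residuals^2) / dfres)
        mis <- !obs
        d[[v]][mis] <- as.vector(X[mis, , drop = FALSE] %*% beta) +
          stats::rnorm(sum(mis), 0, sigma)
      }
    }
    d
  })
}

#' Natural-effect point estimates by counterfactual imputation
#'
#' Regression-based estimation of the total effect (te), natural direct
#' effect (nde), natural indirect effect (nie) and proportion mediated (pm)
#' from one completed dataset. A mediator model `M ~ A + C` and an outcome
#' model `Y ~ A + M (+ A:M) + C` are fitted; for each subject the
#' counterfactual mediator values M(0) and M(1) are simulated from the
#' mediator model (or plugged in as model means), the four potential-outcome
#' means `E[Y(a, M(a*))]` are predicted from the outcome model and averaged
#' over subjects, and the effects are the stated contrasts:
#' `te = E[Y(1,M(1))] - E[Y(0,M(0))]`; under the default decomposition
#' `nie = E[Y(0,M(1))] - E[Y(0,M(0))]` (pure) and
#' `nde = E[Y(1,M(1))] - E[Y(0,M(1))]` (total), which sum to te exactly.
#'
#' @param completed_dataset Data frame with no missing cells in the model
#'   variables.
#' @param spec A [counterfactual_spec()].
#' @param scale_constants Optional list `(min, max)` freezing the 0-100
#'   outcome scaling; computed from the data when `NULL`.
#' @return Named list `te`, `nde`, `nie`, `pm` (pm is `NA` with a warning
#'   when |te| is below 1e-8), plus the four potential-outcome means.
#' @export
counterfactual_effects <- function(completed_dataset, spec,
                                   scale_constants = NULL) {
  stopifnot(inherits(spec, "counterfactual_spec"))
  d <- completed_dataset
  vars <- c(spec$exposure, spec$mediator, spec$outcome, spec$baseline_covariates)
  missing_cols <- setdiff(vars, names(d))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(d[vars])) stop("completed dataset still has missing cells")
  a_vals <- sort(unique(d[[spec$exposure]]))
  if (!identical(as.numeric(a_vals), c(0, 1)))
    stop("exposure must be binary 0/1 with both arms present")
  y <- d[[spec$outcome]]
  if (spec$scale_outcome) {
    sc <- scale_constants %||% list(min = min(y), max = max(y))
    if (sc$max <= sc$min) stop("degenerate outcome scaling")
    d[[spec$outcome]] <- 100 * (y - sc$min) / (sc$max - sc$min)
  }
  covs <- spec$baseline_covariates
  f_m <- stats::reformulate(c(spec$exposure, covs), response = spec$mediator)
  rhs_y <- c(spec$exposure, spec$mediator,
             if (spec$interaction) paste0(spec$exposure, ":", spec$mediator),
             covs)
  f_y <- stats::reformulate(rhs_y, response = spec$outcome)
  fit_m <- stats::lm(f_m, data = d)
  fit_y <- stats::lm(f_y, data = d)
  sigma_m <- summary(fit_m)$sigma
  n <- nrow(d)

  pred_m <- function(a) {
    nd <- d; nd[[spec$exposure]] <- a
    stats::predict(fit_m, newdata = nd)
  }
  pred_y <- function(a, mvals) {
    nd <- d; nd[[spec$exposure]] <- a; nd[[spec$mediator]] <- mvals
    stats::predict(fit_y, newdata = nd)
  }
  m0_mean <- pred_m(0); m1_mean <- pred_m(1)
  ndraw <- spec$mediator_draws
  if (ndraw > 0) {
    # common residual draws across M(0)/M(1) and across the four contrasts
    po <- matrix(0, nrow = 2, ncol = 2,
                 dimnames = list(a = c("0", "1"), mstar = c("0", "1")))
    for (k in seq_len(ndraw)) {
      eps <- stats::rnorm(n, 0, sigma_m)
      m0 <- m0_mean + eps; m1 <- m1_mean + eps
      po["0", "0"] <- po["0", "0"] + mean(pred_y(0, m0))
      po["0", "1"] <- po["0", "1"] + mean(pred_y(0, m1))
      po["1", "0"] <- po["1", "0"] + mean(pred_y(1, m0))
      po["1", "1"] <- po["1", "1"] + mean(pred_y(1, m1))
    }
    po <- po / ndraw
  } else {
    po <- matrix(c(mean(pred_y(0, m0_mean)), mean(pred_y(0, m1_mean)),
                   mean(pred_y(1, m0_mean)), mean(pred_y(1, m1_mean))),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(a = c("0", "1"), mstar = c("0", "1")))
  }
  te <- po["1", "1"] - po["0", "0"]
  if (spec$decomposition == "pure_nie_total_nde") {
    nie <- po["0", "1"] - po["0", "0"]   # pure indirect
    nde <- po["1", "1"] - po["0", "1"]   # total direct
  } else {
    nde <- po["1", "0"] - po["0", "0"]   # pure direct
    nie <- po["1", "1"] - po["1", "0"]   # total indirect
  }
  pm <- if (abs(te) > 1e-8) nie / te else { warning("|te| ~ 0; pm undefined"); NA_real_ }
  list(te = te, nde = nde, nie = nie, pm = pm, potential_outcomes = po)
}

#' Pooled natural effects with bootstrap confidence intervals
#'
#' Full counterfactual mediation analysis on a raw (possibly incomplete)
#' dataset: the outcome scaling constants are frozen from the analysis
#' sample; effects are estimated within each of `n_imputations` completed
#' datasets and pooled by averaging; a nonparametric bootstrap over subjects
#' — with the imputation nested inside each resample — yields percentile
#' confidence intervals and two-sided p-values for te, nde and nie.
#' Resamples missing one of the arms are redrawn. Seed-deterministic.
#'
#' @param spec A [counterfactual_spec()].
#' @param raw_dataset Data frame, possibly with missing mediator/outcome/
#'   covariate cells (never in the arm indicator).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `counterfactual_result`: `te`, `nde`, `nie`, `pm`,
#'   per-effect `ci` and `p`, `per_imputation` estimates, `n_boot`,
#'   `n_imputations`, `seed`.
#' @export
pool_and_ci <- function(spec, raw_dataset, conf_level = 0.95) {
  stopifnot(inherits(spec, "counterfactual_spec"))
  if (anyNA(raw_dataset[[spec$exposure]])) stop("missing arm indicators")
  y <- raw_dataset[[spec$outcome]]
  sc <- if (spec$scale_outcome)
    list(min = min(y, na.rm = TRUE), max = max(y, na.rm = TRUE)) else NULL

  estimate_once <- function(data, seed) {
    completed <- impute_missing(data, spec$n_imputations, seed = seed)
    ests <- lapply(completed, counterfactual_effects, spec = spec,
                   scale_constants = sc)
    list(te = mean(vapply(ests, `[[`, numeric(1), "te")),
         nde = mean(vapply(ests, `[[`, numeric(1), "nde")),
         nie = mean(vapply(ests, `[[`, numeric(1), "nie")),
         per_imputation = ests)
  }

  set.seed(spec$seed)
  point <- estimate_once(raw_dataset, seed = sample.int(2^31 - 1, 1))
  pm <- if (abs(point$te) > 1e-8) point$nie / point$te else NA_real_

  n <- nrow(raw_dataset)
  boots <- matrix(NA_real_, nrow = spec$n_boot, ncol = 3,
                  dimnames = list(NULL, c("te", "nde", "nie")))
  b <- 1L
  while (b <= spec$n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    arm_b <- raw_dataset[[spec$exposure]][idx]
    if (length(unique(arm_b)) < 2) next  # single-arm resample: redraw
    est <- tryCatch(estimate_once(raw_dataset[idx, , drop = FALSE],
                                  seed = sample.int(2^31 - 1, 1)),
                    error = function(e) NULL)
    if (is.null(est)) next
    boots[b, ] <- c(est$te, est$nde, est$nie)
    b <- b + 1L
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  pvals <- apply(boots, 2, function(v) {
    p <- 2 * min(mean(v <= 0), mean(v >= 0))
    min(max(p, 2 / spec$n_boot), 1)
  })
  structure(list(te = point$te, nde = point$nde, nie = point$nie, pm = pm,
                 ci = list(te = unname(ci[, "te"]), nde = unname(ci[, "nde"]),
                           nie = unname(ci[, "nie"])),
                 p = as.list(pvals),
                 per_imputation = point$per_imputation,
                 boot = boots,
                 n_boot = spec$n_boot, n_imputations = spec$n_imputations,
                 seed = spec$seed),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  for (eff in c("te", "nde", "nie"))
    cat(sprintf("%-4s = %8.3f, 95%% CI [%.3f, %.3f], p = %.4f\n", eff,
                x[[eff]], x$ci[[eff]][1], x$ci[[eff]][2], x$p[[eff]]))
  cat(sprintf("pm   = %8.3f\n", x$pm))
  invisible(x)
}
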