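#' Fit the normative exposure-symptom line by OLS on baseline averages
#'
#' The observational-cohort normative model: each participant's mean symptom
#' score P over the first monitoring window (the first three post-baseline
#' monitorings) is regressed on their mean exposure score E over the same
#' window. The fitted line is the sample's normative reactivity; it is stored
#' and later applied to any outcome interval.
#'
#' @param E_baseline,P_baseline Per-participant mean E and mean P (numeric,
#'   equal length, >= 3 complete pairs).
#' @return A `normative_model` of kind `"ols_baseline"` with `b0`, `b1`, `r2`,
#'   and the underlying `lm` fit.
#' @export
fit_normative_ols <- function(E_baseline, P_baseline) {
  ok <- stats::complete.cases(E_baseline, P_baseline)
  E <- as.numeric(E_baseline[ok]); P <- as.numeric(P_baseline[ok])
  if (length(E) < 3) stop("need at least 3 participants with both averages")
  if (stats::sd(E) == 0) stop("zero variance in E; normative line undefined")
  fit <- stats::lm(P ~ E)
  structure(list(kind = "ols_baseline",
                 b0 = unname(stats::coef(fit)[1]),
                 b1 = unname(stats::coef(fit)[2]),
                 r2 = summary(fit)$r.squared,
                 n = length(E), fit = fit),
            class = "normative_model")
}

#' Likelihood-ratio lack-of-fit test for a quadratic exposure term
#'
#' Compares the linear normative model with the same model plus E^2 by a
#' 1-df likelihood-ratio test. Both models are fitted by maximum likelihood
#' (for the mixed-model kind, REML is switched off), as required for LRTs on
#' fixed effects.
#'
#' @param E,P Numeric vectors (per-participant baseline averages for
#'   `kind = "ols_baseline"`, or per-row monitoring values for
#'   `kind = "lmm_random_slope"`).
#' @param kind `"ols_baseline"` (default) or `"lmm_random_slope"`; the latter
#'   requires `id` (participant identifiers) and fits random intercept+slope.
#' @param id Participant identifiers (mixed-model kind only).
#' @return List with `statistic` (chi-square), `df` (always 1), `p`.
#' @export
quadratic_check <- function(E, P, kind = c("ols_baseline", "lmm_random_slope"),
                            id = NULL) {
  kind <- match.arg(kind)
  if (kind == "ols_baseline") {
    ok <- stats::complete.cases(E, P)
    d <- data.frame(E = E[ok], P = P[ok])
    m1 <- stats::lm(P ~ E, data = d)
    m2 <- stats::lm(P ~ E + I(E^2), data = d)
    stat <- as.numeric(2 * (stats::logLik(m2) - stats::logLik(m1)))
  } else {
    if (is.null(id)) stop("mixed-model quadratic check needs participant ids")
    ok <- stats::complete.cases(E, P, id)
    d <- data.frame(E = E[ok], P = P[ok], id = id[ok])
    m1 <- lme4::lmer(P ~ E + (1 + E | id), data = d, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    m2 <- lme4::lmer(P ~ E + I(E^2) + (1 + E | id), data = d, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    stat <- as.numeric(2 * (stats::logLik(m2) - stats::logLik(m1)))
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Interval-level stressor-reactivity scores from a fitted normative line
#'
#' For each participant with at least `min_monitorings` complete monitorings
#' whose `time_index` lies in the interval, SR is the residual of their
#' interval-average symptom score from the normative line at their
#' interval-average exposure: `SR = mean(P) - (b0 + b1 * mean(E))`. Positive
#' SR means more symptoms than exposure-peers (less resilient).
#'
#' @param model A `normative_model` (either kind; the fixed-effect/OLS line is
#'   used).
#' @param monitoring Data frame with `participant_id`, `time_index`, `E`, `P`.
#' @param interval Integer vector of monitoring time indices in the interval,
#'   or a list with `label` and `times`.
#' @param min_monitorings Minimum complete monitorings required (defaults per
#'   interval label: 4 for B0-B2, 3 for B0-B1/B1-B2, 2 for 9-month windows).
#' @return Data frame of class `sr_scores`: `participant_id`, `interval`,
#'   `sr`, `n_monitorings_used`. Empty (with a warning) if nobody survives the
#'   filter.
#' @export
compute_interval_sr <- function(model, monitoring, interval,
                                min_monitorings = 2L) {
  stopifnot(inherits(model, "normative_model"))
  label <- "interval"
  if (is.list(interval) && !is.null(interval$times)) {
    label <- interval$label %||% "interval"
    times <- interval$times
  } else times <- interval
  d <- monitoring[monitoring$time_index %in% times &
                    stats::complete.cases(monitoring[c("E", "P")]), , drop = FALSE]
  if (!nrow(d)) {
    warning("no complete monitorings in interval")
    return(.empty_sr(label))
  }
  d <- unique(d[c("participant_id", "time_index", "E", "P")])
  agg <- do.call(rbind, lapply(split(d, d$participant_id), function(g) {
    data.frame(participant_id = g$participant_id[1],
               mean_E = mean(g$E), mean_P = mean(g$P),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n >= min_monitorings, , drop = FALSE]
  if (!nrow(agg)) {
    warning("no participant meets the minimum-monitoring requirement")
    return(.empty_sr(label))
  }
  out <- data.frame(participant_id = agg$participant_id,
                    interval = label,
                    sr = agg$mean_P - (model$b0 + model$b1 * agg$mean_E),
                    n_monitorings_used = agg$n,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("sr_scores", class(out))
  out
}

.empty_sr <- function(label) {
  out <- data.frame(participant_id = character(0), interval = character(0),
                    sr = numeric(0), n_monitorings_used = integer(0))
  class(out) <- c("sr_scores", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the mixed-model normative exposure-symptom line
#'
#' The trial-dialect normative model: symptom score P is regressed on exposure
#' E across all participants and time points with a participant-level random
#' intercept and random slope. Per-row SR scores are residuals to the
#' fixed-effects (population) line, so that between-person deviation is
#' retained rather than absorbed by the random effects. If the random-slope
#' variance is singular the model falls back to a random intercept only (a
#' message is emitted).
#'
#' @param monitoring Data frame with `participant_id`, `time_index`, `E`, `P`.
#' @return A `normative_model` of kind `"lmm_random_slope"` with `b0`, `b1`,
#'   variance components (`var_fixed`, `var_random`, `var_resid`),
#'   `r2_marginal`, `r2_conditional`, per-row `sr` data frame, and the `lmer`
#'   fit.
#' @export
fit_normative_lmm <- function(monitoring) {
  d <- monitoring[stats::complete.cases(monitoring[c("E", "P")]), , drop = FALSE]
  tpp <- table(d$participant_id)
  if (!any(tpp >= 2)) stop("need repeated measurements for a mixed model")
  fit <- tryCatch(
    lme4::lmer(P ~ E + (1 + E | participant_id), data = d, REML = TRUE),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e)))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    message("singular random-slope variance; refitting with random intercept only")
    fit <- lme4::lmer(P ~ E + (1 | participant_id), data = d, REML = TRUE)
  }
  b <- lme4::fixef(fit)
  sr <- d$P - (b[1] + b[2] * d$E)
  vc <- .lmm_variance_components(fit)
  structure(list(kind = "lmm_random_slope",
                 b0 = unname(b[1]), b1 = unname(b[2]),
                 var_fixed = vc$var_fixed, var_random = vc$var_random,
                 var_resid = vc$var_resid,
                 r2_marginal = vc$r2_marginal, r2_conditional = vc$r2_conditional,
                 n = nrow(d),
                 sr = data.frame(participant_id = d$participant_id,
                                 time_index = d$time_index, sr = sr,
                                 stringsAsFactors = FALSE),
                 fit = fit),
            class = "normative_model")
}

# Nakagawa-style decomposition; random-slope models use the mean row-wise
# Z Sigma Z' (Johnson 2014) for the random-effect variance.
.lmm_variance_components <- function(fit) {
  var_fixed <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  X <- stats::model.matrix(fit)
  var_random <- 0
  for (grp in names(vc)) {
    Sigma <- as.matrix(vc[[grp]])
    zn <- rownames(Sigma)
    Z <- X[, zn, drop = FALSE]
    var_random <- var_random + mean(rowSums((Z %*% Sigma) * Z))
  }
  var_resid <- attr(vc, "sc")^2
  tot <- var_fixed + var_random + var_resid
  list(var_fixed = var_fixed, var_random = var_random, var_resid = var_resid,
       r2_marginal = var_fixed / tot, r2_conditional = (var_fixed + var_random) / tot)
}

#' Marginal and conditional variance explained by a mixed normative model
#'
#' Marginal R2 is the share of total variance attributable to the fixed
#' effects only; conditional R2 additionally credits the random effects:
#' `r2_marginal = var_fixed / (var_fixed + var_random + var_resid)`,
#' `r2_conditional = (var_fixed + var_random) / (same denominator)`.
#'
#' @param model A `normative_model` of kind `"lmm_random_slope"`.
#' @return Named list `r2_marginal`, `r2_conditional`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "normative_model"))
  if (model$kind != "lmm_random_slope")
    stop("variance_explained needs a mixed-model normative fit")
  tot <- model$var_fixed + model$var_random + model$var_resid
  if (tot <= 0) stop("all variance components are zero")
  list(r2_marginal = model$var_fixed / tot,
       r2_conditional = (model$var_fixed + model$var_random) / tot)
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative E-P line (%s): P = %.3f + %.3f * E\n",
              x$kind, x$b0, x$b1))
  if (x$kind == "lmm_random_slope")
    cat(sprintf("  R2 marginal = %.3f, conditional = %.3f (n rows = %d)\n",
                x$r2_marginal, x$r2_conditional, x$n))
  else
    cat(sprintf("  R2 = %.3f (n = %d)\n", x$r2, x$n))
  invisible(x)
}
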