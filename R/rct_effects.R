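#' Group, time, and group-by-time intervention-effect model
#'
#' For one longitudinal trial outcome (E, P, SR, or PAS): a linear mixed
#' model with a participant random intercept, fixed effects for arm, time
#' (continuous linear trend over the assessment points), their interaction,
#' and baseline covariates. Reported with Wald confidence intervals and
#' Satterthwaite p-values; fitted by REML.
#'
#' @param records Long data frame: `participant_id`, `arm` (0/1), `time`
#'   (integer 0..T), `value`, plus covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age, gender, education; silently reduced to those present).
#' @return List of class `group_time_result`: `fixed` data frame (`term`,
#'   `estimate`, `ci_low`, `ci_high`, `p`), the `lmerMod` fit, and `data`.
#' @export
fit_group_time <- function(records, covariates = c("age", "gender", "education")) {
  stopifnot(all(c("participant_id", "arm", "time", "value") %in% names(records)))
  covariates <- intersect(covariates, names(records))
  d <- records[stats::complete.cases(records[c("arm", "time", "value", covariates)]), ]
  if (length(unique(d$arm)) < 2) stop("both arms must be present")
  if (length(unique(d$time)) < 2) stop("need at least 2 time points")
  fml <- stats::reformulate(c("arm * time", covariates, "(1 | participant_id)"),
                            response = "value")
  fit <- tryCatch(lmerTest::lmer(fml, data = d, REML = TRUE),
                  error = function(e) stop("mixed-model fit failed: ",
                                           conditionMessage(e)))
  sm <- stats::coef(summary(fit))
  ci <- stats::confint(fit, parm = "beta_", method = "Wald")
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fixed = fixed, fit = fit, covariates = covariates, data = d),
            class = "group_time_result")
}

#' Estimated marginal means per arm and time point
#'
#' Model-based cell means from a fitted group-by-time model, evaluated at the
#' covariate grand means for each observed arm x time combination, with
#' delta-method (Kenward-Roger/Satterthwaite-df) confidence intervals.
#'
#' @param result A [fit_group_time()] result.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame: `arm`, `time`, `emmean`, `ci_low`, `ci_high`, `n`
#'   (observed cell count).
#' @export
estimated_marginal_means <- function(result, conf_level = 0.95) {
  stopifnot(inherits(result, "group_time_result"))
  d <- result$data
  times <- sort(unique(d$time))
  arms <- sort(unique(d$arm))
  em <- emmeans::emmeans(result$fit, ~ arm * time,
                         at = list(arm = arms, time = times),
                         level = conf_level,
                         lmer.df = "satterthwaite")
  tab <- as.data.frame(em)
  counts <- as.data.frame(table(arm = d$arm, time = d$time),
                          stringsAsFactors = FALSE)
  counts$arm <- as.numeric(counts$arm); counts$time <- as.numeric(counts$time)
  out <- merge(data.frame(arm = tab$arm, time = tab$time, emmean = tab$emmean,
                          ci_low = tab$lower.CL, ci_high = tab$upper.CL),
               counts, by = c("arm", "time"), all.x = TRUE)
  names(out)[names(out) == "Freq"] <- "n"
  out$n[is.na(out$n)] <- 0L
  out <- out[out$n > 0, , drop = FALSE]  # only observed cells
  out[order(out$arm, out$time), , drop = FALSE]
}

#' Prospective prediction of post-baseline SR by baseline PAS
#'
#' Linear mixed model of SR at the post-baseline assessments on the baseline
#' PAS score, with arm and covariates as fixed effects, a random effect for
#' time, and a random intercept for participant nested in arm. If the nested
#' structure is singular (as it easily is with only two arm levels), the
#' model falls back to participant and time random intercepts only, with a
#' message.
#'
#' @param sr_records Long data frame: `participant_id`, `arm`, `time`
#'   (post-baseline points), `sr`, plus `pas_t0` and covariate columns.
#' @param covariates Covariate column names (default age, gender, education).
#' @return List of class `pas_prediction_result`: `estimate`, `ci_low`,
#'   `ci_high`, `p` for the baseline-PAS coefficient, the full `fixed` table,
#'   and the fit.
#' @export
fit_baseline_pas_prediction <- function(sr_records,
                                        covariates = c("age", "gender",
                                                       "education")) {
  stopifnot(all(c("participant_id", "arm", "time", "sr", "pas_t0") %in%
                  names(sr_records)))
  covariates <- intersect(covariates, names(sr_records))
  d <- sr_records[stats::complete.cases(
    sr_records[c("arm", "time", "sr", "pas_t0", covariates)]), ]
  full <- stats::reformulate(
    c("pas_t0", "arm", covariates, "(1 | time)", "(1 | arm:participant_id)"),
    response = "sr")
  fit <- tryCatch(lmerTest::lmer(full, data = d, REML = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    message("nested random structure singular; using participant and time intercepts")
    fallback <- stats::reformulate(
      c("pas_t0", "arm", covariates, "(1 | time)", "(1 | participant_id)"),
      response = "sr")
    fit <- lmerTest::lmer(fallback, data = d,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  sm <- stats::coef(summary(fit))
  ci <- stats::confint(fit, parm = "beta_", method = "Wald")
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  i <- which(fixed$term == "pas_t0")
  structure(list(estimate = fixed$estimate[i], ci_low = fixed$ci_low[i],
                 ci_high = fixed$ci_high[i], p = fixed$p[i],
                 fixed = fixed, fit = fit),
            class = "pas_prediction_result")
}

#' @export
print.group_time_result <- function(x, ...) {
  print(x$fixed, digits = 3)
  invisible(x)
}
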