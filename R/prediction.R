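#' Screen baseline covariates against a reference SR score
#'
#' Age and gender are always retained. Every other candidate is regressed
#' alone on the reference stressor-reactivity score (the longest-interval SR)
#' and kept iff its two-sided slope p-value is below `alpha_screen`
#' (default 0.2). Constant candidates are dropped with a warning.
#'
#' @param candidates Data frame of candidate covariate columns, row-aligned
#'   with `sr_reference`.
#' @param sr_reference Numeric vector of SR scores (the screening outcome).
#' @param alpha_screen Inclusion threshold on the univariate p-value.
#' @param mandatory Character vector of always-included covariate names.
#' @return List of class `covariate_set`: `mandatory`, `screened_in`,
#'   `screen_pvalues` (named), `selected` (mandatory plus screened-in).
#' @export
select_covariates <- function(candidates, sr_reference, alpha_screen = 0.2,
                              mandatory = c("age", "gender")) {
  stopifnot(is.data.frame(candidates) || is.null(candidates))
  pvals <- c()
  screened <- character(0)
  cand_names <- setdiff(names(candidates), mandatory)
  for (nm in cand_names) {
    x <- candidates[[nm]]
    ok <- stats::complete.cases(x, sr_reference)
    if (length(unique(x[ok])) < 2) {
      warning("constant candidate '", nm, "' excluded from screening")
      next
    }
    fit <- stats::lm(sr_reference[ok] ~ x[ok])
    p <- summary(fit)$coefficients[2, 4]
    pvals[nm] <- p
    if (p < alpha_screen) screened <- c(screened, nm)
  }
  structure(list(mandatory = mandatory, screened_in = screened,
                 screen_pvalues = pvals,
                 selected = union(mandatory, screened)),
            class = "covariate_set")
}

#' Standardized-beta regression of SR on a baseline resilience factor
#'
#' Ordinary least squares of an interval SR score on one scored factor plus
#' covariates, on complete cases. Continuous variables (including SR and the
#' predictor) are z-standardized before fitting so coefficients are
#' standardized betas; binary 0/1 columns (e.g. gender) are left as they are,
#' so their beta is a standardized-outcome group contrast.
#'
#' @param data Data frame holding predictor, covariates and the SR outcome.
#' @param predictor Name of the predictor column.
#' @param covariates Character vector of covariate column names (possibly
#'   empty), or a `covariate_set` (its `selected` entry is used).
#' @param outcome Name of the SR outcome column (default `"sr"`).
#' @return List of class `sr_regression`: `coefficients` data frame
#'   (`term`, `beta`, `ci_low`, `ci_high`, `p`), `n`, `r2`, `adj_r2`,
#'   `f_stat`, `f_p`, and the `lm` fit.
#' @export
fit_sr_regression <- function(data, predictor, covariates = character(0),
                              outcome = "sr") {
  if (inherits(covariates, "covariate_set")) covariates <- covariates$selected
  covariates <- intersect(covariates, names(data))
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[vars]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < length(vars) + 1) stop("too few complete cases")
  for (v in vars) {
    x <- d[[v]]
    if (.is_binary(x)) next
    if (stats::sd(x) == 0) stop("constant column '", v, "' cannot be standardized")
    d[[v]] <- as.numeric(scale(x))
  }
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ", paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  structure(list(predictor = predictor, outcome = outcome,
                 coefficients = coefs, n = n,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 f_stat = unname(fstat[1]),
                 f_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                 fit = fit),
            class = "sr_regression")
}

.is_binary <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) == 2 && all(u %in% c(0, 1))
}

#' High-exposure subsample: top two terciles of mean exposure
#'
#' Returns the participants whose mean exposure is at or above the first
#' tercile cut, i.e. the most stressor-exposed upper two-thirds. Ties at the
#' cut are included.
#'
#' @param mean_E Named numeric vector of per-participant mean exposure (names
#'   are participant ids) or a data frame with `participant_id` and `mean_E`.
#' @return Character vector of retained participant ids (or integer indices
#'   when `mean_E` is unnamed).
#' @export
high_exposure_subset <- function(mean_E) {
  if (is.data.frame(mean_E)) {
    ids <- mean_E$participant_id
    vals <- mean_E$mean_E
  } else {
    vals <- mean_E
    ids <- names(mean_E) %||% seq_along(mean_E)
  }
  ok <- !is.na(vals)
  if (sum(ok) < 3) stop("need at least 3 participants")
  cut <- stats::quantile(vals[ok], probs = 1 / 3, names = FALSE)
  ids[ok][vals[ok] >= cut]
}

#' @export
print.sr_regression <- function(x, ...) {
  cat(sprintf("SR ~ %s (+%d covariates), n = %d\n", x$predictor,
              nrow(x$coefficients) - 2L, x$n))
  print(x$coefficients, digits = 3)
  cat(sprintf("R2 = %.3f (adj %.3f), F = %.2f, p = %.3g\n",
              x$r2, x$adj_r2, x$f_stat, x$f_p))
  invisible(x)
}
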