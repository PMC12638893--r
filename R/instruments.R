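#' Define a self-report instrument scoring rule
#'
#' An instrument spec fixes the number of items, the per-item response bounds,
#' whether the total is a sum or a mean, and which items (if any) are
#' reverse-keyed. Scoring is then a pure function of the item matrix.
#'
#' @param name Identifier, e.g. `"pass_content"`.
#' @param n_items Number of items (>= 1).
#' @param item_min,item_max Integer response bounds per item (`item_min < item_max`).
#' @param aggregation `"sum"` or `"mean"`.
#' @param reverse_items Integer indices of reverse-keyed items (subset of
#'   `1:n_items`; empty by default — none of the scales used here document
#'   reverse keys).
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, n_items, item_min, item_max,
                            aggregation = c("sum", "mean"),
                            reverse_items = integer(0)) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.character(name), length(name) == 1L,
            n_items >= 1, item_min < item_max)
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) && !all(reverse_items %in% seq_len(n_items)))
    stop("reverse_items must be a subset of 1..n_items")
  structure(
    list(name = name, n_items = as.integer(n_items),
         item_min = as.integer(item_min), item_max = as.integer(item_max),
         aggregation = aggregation, reverse_items = reverse_items),
    class = "instrument_spec")
}

#' Built-in instrument catalogue
#'
#' Scoring rules for the instruments used across the observational cohorts and
#' the trial: PASS-content (14 items, 1-4, sum, range 14-56), PASS-process
#' (10 items, 1-5, sum, range 10-50), GHQ-28 (28 items, 0-3, sum, range 0-84),
#' PHQ-ADS (16 items, 0-3, sum, range 0-48), perceived social support
#' (14 items, 1-5, mean), Brief Resilience Scale (6 items, 1-5, mean), and the
#' 12-item trial version of PASS-content (range 12-48).
#'
#' @param name Optional instrument name; if given, that single spec is
#'   returned (unknown names error).
#' @return A named list of `instrument_spec` objects, or a single spec.
#' @export
default_instruments <- function(name = NULL) {
  cat_ <- list(
    pass_content    = instrument_spec("pass_content", 14, 1, 4, "sum"),
    pass_content_12 = instrument_spec("pass_content_12", 12, 1, 4, "sum"),
    pass_process    = instrument_spec("pass_process", 10, 1, 5, "sum"),
    ghq28           = instrument_spec("ghq28", 28, 0, 3, "sum"),
    phq_ads         = instrument_spec("phq_ads", 16, 0, 3, "sum"),
    social_support  = instrument_spec("social_support", 14, 1, 5, "mean"),
    brs             = instrument_spec("brs", 6, 1, 5, "mean"))
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_)) stop("unknown instrument: ", name)
  cat_[[name]]
}

#' Score an instrument from item-level responses
#'
#' Reverse-keyed items are recoded as `item_min + item_max - x`, then items are
#' summed or averaged per respondent. A respondent with any missing item gets a
#' missing score: no proration.
#'
#' @param responses Numeric matrix or data frame, respondents x items, with
#'   exactly `spec$n_items` columns.
#' @param spec An [instrument_spec()].
#' @return Numeric vector of per-respondent scores.
#' @examples
#' spec <- default_instruments("pass_content")
#' score_instrument(matrix(4, 3, 14), spec)  # all at item max -> 56
#' @export
score_instrument <- function(responses, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  x <- as.matrix(responses)
  if (ncol(x) != spec$n_items)
    stop(sprintf("'%s' expects %d items, got %d columns",
                 spec$name, spec$n_items, ncol(x)))
  storage.mode(x) <- "double"
  bad <- which(!is.na(x) & (x < spec$item_min | x > spec$item_max), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("out-of-range response for '%s' at row %d, item %d",
                 spec$name, bad[1, 1], bad[1, 2]))
  if (length(spec$reverse_items))
    x[, spec$reverse_items] <- spec$item_min + spec$item_max - x[, spec$reverse_items]
  if (spec$aggregation == "sum") rowSums(x) else rowMeans(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(var_item)/var_total)` with sample (n-1)
#' variances, plus a Feldt-type F confidence interval.
#'
#' @param item_matrix Numeric matrix/data frame, respondents x items; no
#'   missing cells (apply listwise deletion first).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `reliability_result` with `statistic = "alpha"`,
#'   `estimate`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
cronbach_alpha <- function(item_matrix, conf_level = 0.95) {
  x <- as.matrix(item_matrix)
  if (anyNA(x)) stop("item_matrix contains missing cells; delete listwise first")
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need at least 2 items")
  if (n < 3) stop("need at least 3 respondents")
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0) stop("zero total-score variance")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
  # Feldt (1965): (1 - alpha_hat)/(1 - alpha) ~ F(n-1, (n-1)(k-1))
  a2 <- (1 - conf_level) / 2
  ci_low  <- 1 - (1 - alpha) * stats::qf(1 - a2, n - 1, (n - 1) * (k - 1))
  ci_high <- 1 - (1 - alpha) * stats::qf(a2, n - 1, (n - 1) * (k - 1))
  structure(list(statistic = "alpha", estimate = alpha,
                 ci_low = ci_low, ci_high = ci_high, n = n, k = k),
            class = "reliability_result")
}

#' Two-occasion consistency ICC
#'
#' Single-measure consistency intraclass correlation from the two-way ANOVA
#' decomposition over k = 2 measurement occasions (test-retest stability).
#' With between-subject mean square MSB and residual mean square MSE,
#' `ICC = (MSB - MSE) / (MSB + MSE)`, and with `F = MSB/MSE` this satisfies
#' `ICC = (F - 1)/(F + 1)`.
#'
#' @param scores_t1,scores_t2 Paired numeric vectors (complete cases, n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A `reliability_result` with `statistic = "icc"`, `estimate`,
#'   `f_stat`, `df` (= n - 1), `df2`, `ci_low`, `ci_high`, `p`.
#' @export
icc_two_occasion <- function(scores_t1, scores_t2, conf_level = 0.95) {
  ok <- stats::complete.cases(scores_t1, scores_t2)
  y1 <- as.numeric(scores_t1[ok]); y2 <- as.numeric(scores_t2[ok])
  n <- length(y1)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  subj_mean <- (y1 + y2) / 2
  occ_mean <- c(mean(y1), mean(y2))
  grand <- mean(subj_mean)
  ss_subj <- k * sum((subj_mean - grand)^2)
  ss_occ <- n * sum((occ_mean - grand)^2)
  ss_tot <- sum((c(y1, y2) - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_occ
  msb <- ss_subj / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msb <= mse && msb <= .Machine$double.eps) {
    warning("zero between-subject variance; ICC set to 0")
    return(structure(list(statistic = "icc", estimate = 0, f_stat = NA_real_,
                          df = n - 1L, df2 = (n - 1L) * (k - 1L),
                          ci_low = NA_real_, ci_high = NA_real_, p = NA_real_),
                     class = "reliability_result"))
  }
  if (mse <= .Machine$double.eps * max(msb, 1)) {
    # identical occasions: perfect consistency
    return(structure(list(statistic = "icc", estimate = 1, f_stat = Inf,
                          df = as.integer(n - 1), df2 = as.integer(n - 1),
                          ci_low = 1, ci_high = 1, p = 0),
                     class = "reliability_result"))
  }
  f_stat <- msb / mse
  icc <- (f_stat - 1) / (f_stat + 1)
  a2 <- (1 - conf_level) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f_stat / stats::qf(1 - a2, df1, df2)
  fu <- f_stat * stats::qf(1 - a2, df2, df1)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = "icc", estimate = icc, f_stat = f_stat,
                 df = as.integer(df1), df2 = as.integer(df2),
                 ci_low = (fl - 1) / (fl + 1), ci_high = (fu - 1) / (fu + 1),
                 p = p),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s = %.3f", x$statistic, x$estimate))
  if (!is.null(x$ci_low) && !is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci_low, x$ci_high))
  if (!is.null(x$f_stat) && !is.na(x$f_stat))
    cat(sprintf(", F(%d) = %.2f", x$df, x$f_stat))
  cat("\n")
  invisible(x)
}
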