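#' Aggregate stressor reports into exposure scores (z-score-mean dialect)
#'
#' The observational-cohort dialect: at each monitoring time point a
#' participant's life-event count (number of events reported) and daily-hassle
#' day sum (days per past week summed over reported hassles) are each
#' z-standardized over a pool of rows, and the exposure score E is the mean of
#' the two z-scores. Severity ratings are deliberately not used, so that E
#' quantifies exposure independent of burden appraisal.
#'
#' @param reports Data frame with `participant_id`, `time_index`, and either
#'   precomputed `le_count`/`dh_daysum` columns or item-level columns matching
#'   `le_prefix`/`dh_prefix` (life-event occurrence 0/1 flags; hassle day
#'   counts 0-7). Severity columns (`*_sev_*`) are ignored.
#' @param pool `"all"` (default) standardizes over every row of the estimation
#'   window jointly; `"timepoint"` standardizes within each `time_index`.
#' @param le_prefix,dh_prefix Column-name prefixes for item-level input.
#' @param constants Optional list with `le_mean`, `le_sd`, `dh_mean`, `dh_sd`
#'   to apply frozen standardization constants (e.g. from the normative-model
#'   estimation window) instead of recomputing them.
#' @return Data frame: `participant_id`, `time_index`, `E`, `le_count`,
#'   `dh_daysum`, plus attribute `"constants"` holding the standardization
#'   constants used.
#' @details A component with zero standard deviation in the pool yields z = 0
#'   for all rows of that pool, with a warning. Sample (n-1) SDs are used.
#' @export
freshmo_exposure <- function(reports, pool = c("all", "timepoint"),
                             le_prefix = "le_", dh_prefix = "dh_",
                             constants = NULL) {
  pool <- match.arg(pool)
  stopifnot(all(c("participant_id", "time_index") %in% names(reports)))
  comp <- .stressor_components(reports, le_prefix, dh_prefix)
  out <- data.frame(participant_id = reports$participant_id,
                    time_index = reports$time_index,
                    le_count = comp$le, dh_daysum = comp$dh,
                    stringsAsFactors = FALSE)
  zscore <- function(x, m, s, what) {
    if (is.na(s) || s == 0) {
      warning("zero standard deviation in ", what, "; z set to 0")
      return(rep(0, length(x)))
    }
    (x - m) / s
  }
  if (!is.null(constants)) {
    z_le <- zscore(out$le_count, constants$le_mean, constants$le_sd, "life events")
    z_dh <- zscore(out$dh_daysum, constants$dh_mean, constants$dh_sd, "daily hassles")
    used <- constants
  } else if (pool == "all") {
    used <- list(le_mean = mean(out$le_count), le_sd = stats::sd(out$le_count),
                 dh_mean = mean(out$dh_daysum), dh_sd = stats::sd(out$dh_daysum))
    z_le <- zscore(out$le_count, used$le_mean, used$le_sd, "life events")
    z_dh <- zscore(out$dh_daysum, used$dh_mean, used$dh_sd, "daily hassles")
  } else {
    z_le <- z_dh <- rep(NA_real_, nrow(out))
    for (t in unique(out$time_index)) {
      i <- out$time_index == t
      z_le[i] <- zscore(out$le_count[i], mean(out$le_count[i]),
                        stats::sd(out$le_count[i]), paste("life events, t =", t))
      z_dh[i] <- zscore(out$dh_daysum[i], mean(out$dh_daysum[i]),
                        stats::sd(out$dh_daysum[i]), paste("daily hassles, t =", t))
    }
    used <- NULL
  }
  out$E <- (z_le + z_dh) / 2
  out <- out[c("participant_id", "time_index", "E", "le_count", "dh_daysum")]
  attr(out, "constants") <- used
  attr(out, "dialect") <- "freshmo_z"
  out
}

#' Aggregate stressor reports into exposure scores (dichotomized-sum dialect)
#'
#' The trial dialect: 3 life events rated 0 ("did not happen") to 4 ("severe
#' impact") are dichotomized (rating >= 1 counts as occurred) and summed
#' (component max 3); 15 daily-hassle frequencies rated 0-3 are summed
#' (component max 45); E is the total, so 0 <= E <= 48.
#'
#' @param reports Data frame with `participant_id`, `time_index` and item
#'   columns matching `le_prefix` (ratings 0-4) and `dh_prefix`
#'   (frequencies 0-3).
#' @param le_prefix,dh_prefix Column-name prefixes.
#' @return Data frame: `participant_id`, `time_index`, `E`, `le_count`
#'   (dichotomized sum), `dh_sum`.
#' @export
respond_exposure <- function(reports, le_prefix = "le_", dh_prefix = "dh_") {
  stopifnot(all(c("participant_id", "time_index") %in% names(reports)))
  le_cols <- .item_cols(reports, le_prefix)
  dh_cols <- .item_cols(reports, dh_prefix)
  if (!length(le_cols) || !length(dh_cols))
    stop("no life-event or daily-hassle item columns found")
  le <- as.matrix(reports[le_cols]); dh <- as.matrix(reports[dh_cols])
  if (any(le < 0 | le > 4, na.rm = TRUE))
    stop("life-event ratings must be in 0..4")
  if (any(dh < 0 | dh > 3, na.rm = TRUE))
    stop("daily-hassle frequencies must be in 0..3")
  le_count <- rowSums(le >= 1)
  dh_sum <- rowSums(dh)
  data.frame(participant_id = reports$participant_id,
             time_index = reports$time_index,
             E = le_count + dh_sum, le_count = le_count, dh_sum = dh_sum,
             stringsAsFactors = FALSE)
}

#' Per-item stressor frequency and severity descriptives
#'
#' Summarizes each stressor item over all reports: mean and SD of its
#' occurrence value (count per window, days per week, or frequency rating,
#' whichever the dialect records) and mean and SD of severity among occasions
#' on which the item was reported. Sorted by descending mean occurrence.
#'
#' @param reports Data frame with item columns matching `prefix` and,
#'   optionally, matching severity columns named `<prefix>sev_<i>`.
#' @param prefix Item-column prefix (e.g. `"le_"` or `"dh_"`).
#' @return Data frame: `item`, `freq_mean`, `freq_sd`, `sev_mean`, `sev_sd`,
#'   `n_reported`. Severity summaries are `NA` for never-reported items.
#' @export
stressor_descriptives <- function(reports, prefix = "le_") {
  cols <- .item_cols(reports, prefix)
  if (!length(cols) || !nrow(reports))
    return(data.frame(item = character(0), freq_mean = numeric(0),
                      freq_sd = numeric(0), sev_mean = numeric(0),
                      sev_sd = numeric(0), n_reported = integer(0)))
  out <- do.call(rbind, lapply(cols, function(cl) {
    x <- reports[[cl]]
    sev_col <- sub(paste0("^", prefix), paste0(prefix, "sev_"), cl)
    reported <- !is.na(x) & x > 0
    sev_mean <- sev_sd <- NA_real_
    if (sev_col %in% names(reports) && any(reported)) {
      sv <- reports[[sev_col]][reported]
      sv <- sv[!is.na(sv)]
      if (length(sv)) { sev_mean <- mean(sv); sev_sd <- stats::sd(sv) }
    }
    data.frame(item = cl, freq_mean = mean(x, na.rm = TRUE),
               freq_sd = stats::sd(x[!is.na(x)]),
               sev_mean = sev_mean, sev_sd = sev_sd,
               n_reported = sum(reported), stringsAsFactors = FALSE)
  }))
  out[order(-out$freq_mean), , drop = FALSE]
}

# item columns with the given prefix, excluding severity columns
.item_cols <- function(df, prefix) {
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(df), value = TRUE)
  cols[order(as.integer(sub(paste0("^", prefix), "", cols)))]
}

.stressor_components <- function(reports, le_prefix, dh_prefix) {
  if (all(c("le_count", "dh_daysum") %in% names(reports)))
    return(list(le = reports$le_count, dh = reports$dh_daysum))
  le_cols <- .item_cols(reports, le_prefix)
  dh_cols <- .item_cols(reports, dh_prefix)
  if (!length(le_cols) || !length(dh_cols))
    stop("need either le_count/dh_daysum columns or item-level le_*/dh_* columns")
  le <- as.matrix(reports[le_cols]); dh <- as.matrix(reports[dh_cols])
  if (any(dh < 0 | dh > 7, na.rm = TRUE))
    stop("daily-hassle day counts must be in 0..7")
  # life-event component: total number of events reported in the window
  list(le = rowSums(le), dh = rowSums(dh))
}
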