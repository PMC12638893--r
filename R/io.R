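#' Read and validate a monitoring table
#'
#' Long CSV with one row per participant x monitoring time point. Required
#' columns: `participant_id`, `time_index`, plus either `E` and `P` or raw
#' item columns (`le_*`, `dh_*`) and `P`. Duplicate
#' (participant, time) keys and negative time indices are integrity errors;
#' offending line numbers are reported.
#'
#' @param path CSV file path (UTF-8, comma-separated, '.' decimal, empty
#'   cell = missing).
#' @return Validated data frame.
#' @examples
#' f <- system.file("extdata", "monitoring_synthetic_example.csv",
#'                  package = "resil")
#' head(read_monitoring(f))
#' @export
read_monitoring <- function(path) {
  d <- .read_csv(path)
  .require_cols(d, c("participant_id", "time_index"), path)
  if (!("P" %in% names(d)))
    stop("schema error in ", path, ": missing required column \"P\"")
  if (!("E" %in% names(d)) && !length(.item_cols(d, "le_")))
    stop("schema error in ", path,
         ": need column \"E\" or item columns le_*/dh_*")
  .check_keys(d, c("participant_id", "time_index"), path)
  bad <- which(!is.na(d$time_index) & d$time_index < 0)
  if (length(bad))
    stop("integrity error in ", path, ": negative time_index at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  d
}

#' Read and validate a battery table
#'
#' Wide CSV with one row per participant x battery wave. Required columns:
#' `participant_id`, `wave`; duplicate (participant, wave) keys are
#' integrity errors.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @examples
#' f <- system.file("extdata", "battery_synthetic_example.csv",
#'                  package = "resil")
#' head(read_battery(f))
#' @export
read_battery <- function(path) {
  d <- .read_csv(path)
  .require_cols(d, c("participant_id", "wave"), path)
  .check_keys(d, c("participant_id", "wave"), path)
  d
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_cols <- function(d, cols, path) {
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing required column(s) ",
         paste(sprintf('"%s"', missing_cols), collapse = ", "))
}

.check_keys <- function(d, keys, path) {
  dup <- duplicated(d[keys])
  if (any(dup))
    stop("integrity error in ", path, ": duplicate key at line(s) ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
}

#' Default observational run configuration
#'
#' Interval definitions follow the monitoring design: `B0-B2` = T1..T12
#' (minimum 4 monitorings), `B0-B1` = T1..T6 and `B1-B2` = T7..T12 (minimum
#' 3), `post_B0_9m` = T1..T3 (minimum 2). The acquaintance monitoring T0 is
#' excluded from analysis. The normative line is estimated on the T1..T3
#' averages.
#'
#' @param dialect `"freshmo"` or `"respond"` exposure scoring.
#' @param intervals Named list of `list(times, min_monitorings)`.
#' @param estimation_times Time indices of the normative-line window.
#' @param candidate_covariates Covariates offered to the screening step.
#' @param seed Integer seed for stochastic stages.
#' @param output_dir Output directory (`NULL` = no files written).
#' @return List of class `run_config`.
#' @export
run_config <- function(dialect = c("freshmo", "respond"),
                       intervals = list(
                         `B0-B2` = list(times = 1:12, min_monitorings = 4),
                         `B0-B1` = list(times = 1:6, min_monitorings = 3),
                         `B1-B2` = list(times = 7:12, min_monitorings = 3),
                         post_B0_9m = list(times = 1:3, min_monitorings = 2)),
                       estimation_times = 1:3,
                       candidate_covariates = c("childhood_trauma", "smoking",
                                                "income"),
                       seed = 1L, output_dir = NULL) {
  dialect <- match.arg(dialect)
  for (nm in names(intervals))
    if (is.null(intervals[[nm]]$times))
      stop("interval '", nm, "' has no time-index set")
  structure(list(dialect = dialect, intervals = intervals,
                 estimation_times = estimation_times,
                 candidate_covariates = candidate_covariates,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the observational analysis pipeline end to end
#'
#' Stages, in dependency order: exposure scoring -> normative-line estimation
#' on the configured window -> interval SR scores -> covariate screening
#' against the longest-interval SR -> standardized-beta prediction models for
#' each battery factor -> bootstrap mediation (support -> PAS -> SR and
#' PAS -> recovery -> SR). When `config$output_dir` is set, SR tables,
#' regression tables and a mediation JSON are written there along with a
#' manifest listing per-stage row counts, the seed and md5 checksums of every
#' output file.
#'
#' @param monitoring Monitoring data frame (as from [read_monitoring()] or
#'   [generate_observational()]).
#' @param battery Battery data frame.
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `exposure`, `normative`,
#'   `quadratic`, `sr` (named by interval), `covariates`, `regressions`,
#'   `mediation`, `manifest`.
#' @export
run_observational_pipeline <- function(monitoring, battery,
                                       config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_ <- list()
  note <- function(stage, n_in, n_out)
    log_[[stage]] <<- list(stage = stage, n_in = n_in, n_out = n_out,
                           seed = config$seed)

  analysed <- monitoring[monitoring$time_index >= 1, , drop = FALSE]
  exposure <- if (config$dialect == "freshmo")
    freshmo_exposure(analysed) else respond_exposure(analysed)
  ep <- merge(exposure[c("participant_id", "time_index", "E")],
              analysed[c("participant_id", "time_index", "P")],
              by = c("participant_id", "time_index"))
  note("exposure", nrow(analysed), nrow(ep))

  est <- ep[ep$time_index %in% config$estimation_times, , drop = FALSE]
  agg <- stats::aggregate(cbind(E, P) ~ participant_id, data = est, FUN = mean)
  normative <- fit_normative_ols(agg$E, agg$P)
  quadratic <- quadratic_check(agg$E, agg$P, kind = "ols_baseline")
  note("normative", nrow(est), normative$n)

  sr <- lapply(names(config$intervals), function(nm) {
    iv <- config$intervals[[nm]]
    compute_interval_sr(normative, ep,
                        interval = list(label = nm, times = iv$times),
                        min_monitorings = iv$min_monitorings %||% 2L)
  })
  names(sr) <- names(config$intervals)
  note("sr", nrow(ep), sum(vapply(sr, nrow, integer(1))))

  b0 <- battery[battery$wave == "B0", , drop = FALSE]
  ref_interval <- names(config$intervals)[1]
  ref <- merge(b0, sr[[ref_interval]], by = "participant_id")
  cand <- intersect(config$candidate_covariates, names(ref))
  covset <- select_covariates(ref[cand], ref$sr)
  note("screening", nrow(ref), length(covset$selected))

  predictors <- intersect(c("pas_content", "pas_process", "social_support",
                            "recovery"), names(ref))
  regressions <- lapply(predictors, function(p)
    fit_sr_regression(ref, p, covset))
  names(regressions) <- predictors
  note("prediction", nrow(ref), length(regressions))

  mediation <- list(
    support_pas_sr = bootstrap_indirect(ref$social_support, ref$pas_content,
                                        ref$sr, n_boot = 1000,
                                        seed = config$seed),
    pas_recovery_sr = bootstrap_indirect(ref$pas_content, ref$recovery,
                                         ref$sr, n_boot = 1000,
                                         seed = config$seed))
  note("mediation", nrow(ref), length(mediation))

  result <- structure(list(exposure = exposure, normative = normative,
                           quadratic = quadratic, sr = sr,
                           covariates = covset, regressions = regressions,
                           mediation = mediation,
                           manifest = list(stages = log_, seed = config$seed)),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) result <- .write_bundle(result, config)
  result
}

# write tables + manifest atomically (tmp dir, then rename into place)
.write_bundle <- function(result, config) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("bundle_", tmpdir = out)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)

  for (nm in names(result$sr))
    utils::write.csv(result$sr[[nm]],
                     file.path(tmp, paste0("sr_", gsub("[^A-Za-z0-9]", "_", nm),
                                           ".csv")), row.names = FALSE)
  reg <- do.call(rbind, lapply(names(result$regressions), function(p) {
    r <- result$regressions[[p]]
    cbind(predictor = p, r$coefficients, n = r$n, r2 = r$r2,
          adj_r2 = r$adj_r2)
  }))
  utils::write.csv(reg, file.path(tmp, "regressions.csv"), row.names = FALSE)
  med <- lapply(result$mediation, function(m)
    list(a = m$a, b = m$b, c = m$c, c_prime = m$c_prime, ab_mean = m$ab_mean,
         ab_ci = m$ab_ci, n_boot = m$n_boot, seed = m$seed))
  jsonlite::write_json(med, file.path(tmp, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(b0 = result$normative$b0, b1 = result$normative$b1,
                            r2 = result$normative$r2,
                            quadratic = result$quadratic),
                       file.path(tmp, "normative_model.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(tmp, full.names = TRUE)
  manifest <- list(seed = config$seed, dialect = config$dialect,
                   stages = result$manifest$stages,
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)),
                          bytes = file.size(f))))
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in list.files(tmp, full.names = TRUE))
    file.rename(f, file.path(out, basename(f)))
  unlink(tmp, recursive = TRUE)
  ok <- TRUE
  result$manifest <- manifest
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Observational pipeline result\n")
  print(x$normative)
  cat("SR intervals:", paste(sprintf("%s (n=%d)", names(x$sr),
                                     vapply(x$sr, nrow, integer(1))),
                             collapse = ", "), "\n")
  invisible(x)
}
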