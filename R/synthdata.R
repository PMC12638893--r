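#' Configuration for a synthetic observational monitoring cohort
#'
#' Defaults emulate the observational designs the package analyzes: ~1000
#' participants (the replication-cohort scale), 13 three-monthly monitorings
#' T0..T12 with battery waves B0/B1/B2 at T0/T6/T12 (a ~3-year span), GHQ-like
#' symptom scores, 27 life-event and 58 daily-hassle items with rates matched
#' to the printed stressor descriptives, and a latent chain
#' social support -> PAS -> {stress recovery, reactivity}. Path coefficients
#' are on the standardized latent scale; the total standardized PAS ->
#' reactivity path is `g1 + g2 * a2` (-0.3 at the defaults, matching the
#' reported standardized PAS beta).
#'
#' @param n_participants,n_timepoints Cohort size and monitoring count.
#' @param battery_waves Named integer vector mapping wave labels to monitoring
#'   time indices.
#' @param b0_P,slope_EP,sd_resid_P Normative-line intercept, slope (symptom
#'   units per E unit) and residual SD of the symptom score.
#' @param sd_reactivity SD (symptom units) of the stable person-level
#'   reactivity offset entering P additively.
#' @param a1 social support -> PAS; `a2` PAS -> recovery; `g1` PAS ->
#'   reactivity (direct); `g2` recovery -> reactivity. All standardized.
#' @param sd_exposure_propensity SD of the person-level log-rate shift that
#'   creates between-person exposure differences.
#' @param le_rates Per-item life-event Poisson rates (length 27 by default).
#' @param dh_probs Per-item daily-hassle day probabilities (binomial over 7
#'   days; length 58 by default).
#' @param missing_rate Probability that a participant skips a monitoring.
#' @param wave_reliability Test-retest reliability of battery trait scores
#'   across waves (1 = no occasion noise, the default; lower values add
#'   occasion-specific noise for reliability stress tests).
#' @param seed Integer RNG seed.
#' @return List of class `observational_config`.
#' @export
observational_config <- function(n_participants = 1000, n_timepoints = 13,
                                 battery_waves = c(B0 = 0, B1 = 6, B2 = 12),
                                 b0_P = 17, slope_EP = 4, sd_resid_P = 6,
                                 sd_reactivity = 4,
                                 a1 = 0.5, a2 = 0.5, g1 = -0.2, g2 = -0.2,
                                 sd_exposure_propensity = 0.4,
                                 le_rates = 0.5 * 0.87^(0:26),
                                 dh_probs = seq(0.64, 0.04, length.out = 58),
                                 missing_rate = 0.1,
                                 wave_reliability = 1,
                                 seed = 1L) {
  stopifnot(n_participants >= 3, n_timepoints >= 2,
            all(battery_waves >= 0), all(battery_waves < n_timepoints),
            all(le_rates >= 0), all(dh_probs >= 0 & dh_probs <= 1),
            missing_rate >= 0, missing_rate < 1,
            wave_reliability > 0, wave_reliability <= 1,
            sd_resid_P >= 0, sd_reactivity >= 0)
  if (abs(a1) > 1 || abs(a2) > 1) stop("standardized paths a1, a2 must be in [-1, 1]")
  su2 <- 1 - (g1^2 + g2^2 + 2 * g1 * g2 * a2)
  if (su2 < 0) stop("infeasible reactivity paths: implied residual variance < 0")
  structure(as.list(environment()), class = "observational_config")
}

#' Generate a synthetic observational monitoring cohort
#'
#' Draws the latent chain, item-level stressor reports, and symptom scores
#' `P = b0_P + slope_EP * E + r_i + noise`, where E is the z-score-mean
#' exposure computed from the generated counts and `r_i` is the person-level
#' reactivity offset loaded on PAS and recovery. Severity ratings are
#' generated but never enter E. Deterministic under the config seed.
#'
#' @param config An [observational_config()].
#' @return List: `monitoring` (long data frame with item columns `le_*`,
#'   `le_sev_*`, `dh_*` and the symptom score `P`), `battery` (wide per
#'   participant x wave trait scores and covariates, including
#'   `n_monitorings`), `truth` (latent values and the implied planted
#'   standardized PAS->reactivity effect), `config`.
#' @export
generate_observational <- function(config = observational_config()) {
  stopifnot(inherits(config, "observational_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_participants
  k_le <- length(cfg$le_rates); k_dh <- length(cfg$dh_probs)

  # latent chain (standardized)
  S <- stats::rnorm(n)
  PAS <- cfg$a1 * S + stats::rnorm(n, sd = sqrt(1 - cfg$a1^2))
  REC <- cfg$a2 * PAS + stats::rnorm(n, sd = sqrt(1 - cfg$a2^2))
  su2 <- 1 - (cfg$g1^2 + cfg$g2^2 + 2 * cfg$g1 * cfg$g2 * cfg$a2)
  u <- cfg$g1 * PAS + cfg$g2 * REC + stats::rnorm(n, sd = sqrt(su2))
  r_i <- cfg$sd_reactivity * u
  x_i <- stats::rnorm(n, sd = cfg$sd_exposure_propensity)

  pid <- sprintf("p%04d", seq_len(n))
  grid <- expand.grid(row = seq_len(n), time_index = 0:(cfg$n_timepoints - 1))
  nr <- nrow(grid)
  rate_mult <- exp(x_i[grid$row])

  le <- matrix(0L, nr, k_le)
  le_sev <- matrix(NA_real_, nr, k_le)
  le_sev_mean <- seq(4.0, 2.5, length.out = k_le)
  for (j in seq_len(k_le)) {
    le[, j] <- stats::rpois(nr, cfg$le_rates[j] * rate_mult)
    occ <- le[, j] > 0
    if (any(occ))
      le_sev[occ, j] <- pmin(5, pmax(1, round(stats::rnorm(sum(occ),
                                                           le_sev_mean[j], 1))))
  }
  dh <- matrix(0L, nr, k_dh)
  for (j in seq_len(k_dh)) {
    p <- stats::plogis(stats::qlogis(cfg$dh_probs[j]) + 0.5 * x_i[grid$row])
    dh[, j] <- stats::rbinom(nr, 7, p)
  }

  le_count <- rowSums(le)
  dh_daysum <- rowSums(dh)
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  E <- (z(le_count) + z(dh_daysum)) / 2
  P <- cfg$b0_P + cfg$slope_EP * E + r_i[grid$row] +
    stats::rnorm(nr, sd = cfg$sd_resid_P)
  P <- pmax(0, P)

  monitoring <- data.frame(participant_id = pid[grid$row],
                           time_index = grid$time_index,
                           P = P, stringsAsFactors = FALSE)
  colnames(le) <- paste0("le_", seq_len(k_le))
  colnames(le_sev) <- paste0("le_sev_", seq_len(k_le))
  colnames(dh) <- paste0("dh_", seq_len(k_dh))
  monitoring <- cbind(monitoring, le, le_sev, dh)

  keep <- stats::runif(nr) >= cfg$missing_rate
  keep[grid$time_index == 0] <- TRUE  # the acquaintance monitoring always exists
  monitoring <- monitoring[keep, , drop = FALSE]
  rownames(monitoring) <- NULL

  waves <- names(cfg$battery_waves)
  occ_sd <- sqrt(1 / cfg$wave_reliability - 1)
  battery <- do.call(rbind, lapply(waves, function(w) {
    eps <- function() if (occ_sd > 0) stats::rnorm(n, sd = occ_sd) else numeric(n)
    pas_w <- PAS + eps(); rec_w <- REC + eps(); sup_w <- S + eps()
    proc_w <- 0.55 * PAS + sqrt(1 - 0.55^2) * stats::rnorm(n) + eps()
    data.frame(participant_id = pid, wave = w,
               pas_content = 35 + 6 * pas_w,
               pas_process = 30 + 5 * proc_w,
               social_support = 3.5 + 0.6 * sup_w,
               recovery = 3.3 + 0.7 * rec_w,
               stringsAsFactors = FALSE)
  }))
  covs <- data.frame(participant_id = pid,
                     age = round(pmin(50, pmax(18, stats::rnorm(n, 28.8, 8)))),
                     gender = stats::rbinom(n, 1, 0.66),
                     childhood_trauma = round(pmax(25, stats::rnorm(n, 31, 7))),
                     smoking = stats::rpois(n, 2),
                     income = sample(1:6, n, replace = TRUE),
                     stringsAsFactors = FALSE)
  post <- monitoring$time_index >= 1
  nmon <- table(factor(monitoring$participant_id[post], levels = pid))
  covs$n_monitorings <- as.integer(nmon)
  battery <- merge(battery, covs, by = "participant_id", sort = FALSE)
  battery <- battery[order(battery$wave, battery$participant_id), ]
  rownames(battery) <- NULL

  list(monitoring = monitoring, battery = battery,
       truth = list(S = S, PAS = PAS, REC = REC, reactivity = r_i,
                    exposure_propensity = x_i,
                    pas_sr_std = cfg$g1 + cfg$g2 * cfg$a2),
       config = cfg)
}

#' Configuration for a synthetic two-arm four-timepoint trial
#'
#' Defaults emulate the trial design: 116 per arm, four assessments T0..T3,
#' 1:1 allocation, a PAS sum score on the 12-48 scale that rises by
#' `pas_gain` per time step in the intervention arm only, and a stressor-
#' reactivity outcome driven by the previous time point's PAS
#' (`b_pas_sr` < 0) plus a direct intervention effect `direct_gain` per
#' step. At the defaults the planted mediated proportion of the T3 total
#' effect through PAS at T2 is `(2 b_pas_sr pas_gain) /
#' (3 direct_gain + 2 b_pas_sr pas_gain)` = 0.4.
#'
#' @param n_per_arm Participants per arm.
#' @param pas_gain Intervention effect on PAS per time step (scale points).
#' @param direct_gain Intervention effect on SR per time step not routed
#'   through PAS (SR units).
#' @param b_pas_sr SR units per PAS point (negative: higher PAS, lower
#'   reactivity).
#' @param b0_P,slope_P Normative line generating the symptom score
#'   `P = b0_P + slope_P * E + SR`.
#' @param sd_pas_occasion,sd_sr_resid,sd_sr_person Occasion noise of PAS,
#'   residual SD of SR, and SD of the stable person-level SR offset.
#' @param missing_rate MCAR missingness of post-baseline PAS/SR/P/E values.
#' @param seed Integer RNG seed.
#' @return List of class `rct_config`. Timepoints are fixed at 4 (T0..T3).
#' @export
rct_config <- function(n_per_arm = 116, pas_gain = 1.0, direct_gain = -0.5,
                       b_pas_sr = -0.5, b0_P = 8, slope_P = 0.9,
                       sd_pas_occasion = 2, sd_sr_resid = 3, sd_sr_person = 2,
                       missing_rate = 0.2, seed = 1L) {
  stopifnot(n_per_arm >= 3, missing_rate >= 0, missing_rate < 1,
            sd_pas_occasion >= 0, sd_sr_resid >= 0, sd_sr_person >= 0)
  cfg <- as.list(environment())
  cfg$timepoints <- 4L
  structure(cfg, class = "rct_config")
}

#' Generate a synthetic two-arm trial
#'
#' Arms are assigned exactly 1:1. PAS trajectories are flat in the control
#' arm and rise by `pas_gain` per step under intervention; SR at each
#' post-baseline time point is `person offset + b_pas_sr * (PAS at t-1 -
#' scale center) + direct_gain * arm * t + noise`; item-level stressor
#' reports (3 life events rated 0-4, 15 hassle frequencies 0-3) produce E via
#' the dichotomized-sum scorer, and `P = b0_P + slope_P * E + SR`.
#' Missingness is MCAR on post-baseline outcome values. Deterministic under
#' the config seed.
#'
#' @param config An [rct_config()].
#' @return List: `long` (one row per participant x time x outcome with
#'   `outcome_name` in E/P/SR/PAS and covariates), `wide` (analysis table
#'   `participant_id, arm, age, gender, education, pas_t0, sr_t0, pas_t2,
#'   sr_t3`), `items` (raw stressor item reports), `truth` (planted te, nde,
#'   nie, pm at T3), `config`.
#' @export
generate_rct <- function(config = rct_config()) {
  stopifnot(inherits(config, "rct_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- 2L * cfg$n_per_arm
  tt <- 0:(cfg$timepoints - 1L)
  pid <- sprintf("r%04d", seq_len(n))
  arm <- sample(rep(c(0L, 1L), cfg$n_per_arm))  # exact 1:1 allocation
  age <- round(pmin(67, pmax(22, stats::rnorm(n, 37.5, 10.3))))
  gender <- stats::rbinom(n, 1, 0.86)
  education <- sample(0:2, n, replace = TRUE, prob = c(0.18, 0.50, 0.32))

  pas0 <- pmin(48, pmax(12, stats::rnorm(n, 33, 6)))
  u_i <- stats::rnorm(n, sd = cfg$sd_sr_person)
  x_i <- stats::rnorm(n, sd = 0.5)  # exposure propensity

  PASm <- sapply(tt, function(t)
    pas0 + cfg$pas_gain * arm * t +
      if (t > 0) stats::rnorm(n, sd = cfg$sd_pas_occasion) else 0)
  SRm <- sapply(tt, function(t) {
    pas_prev <- if (t == 0) pas0 else PASm[, t]  # column t == time t-1
    u_i + cfg$b_pas_sr * (pas_prev - 33) + cfg$direct_gain * arm * t +
      stats::rnorm(n, sd = cfg$sd_sr_resid)
  })

  # item-level stressor reports -> E by the dichotomized-sum dialect
  items <- do.call(rbind, lapply(tt, function(t) {
    lp <- 0.6 * x_i - 0.15 * t - 0.06 * arm * t
    le <- sapply(1:3, function(j) {
      occ <- stats::rbinom(n, 1, stats::plogis(-0.8 + lp))
      occ * sample(1:4, n, replace = TRUE, prob = c(0.25, 0.35, 0.3, 0.1))
    })
    dh <- sapply(1:15, function(j)
      stats::rbinom(n, 3, stats::plogis(stats::qlogis(0.3) - 0.12 * (j - 1) + lp)))
    out <- data.frame(participant_id = pid, time_index = t,
                      stringsAsFactors = FALSE)
    colnames(le) <- paste0("le_", 1:3); colnames(dh) <- paste0("dh_", 1:15)
    cbind(out, le, dh)
  }))
  Escore <- respond_exposure(items)
  Em <- matrix(Escore$E[order(Escore$time_index, Escore$participant_id)],
               nrow = n)
  Pm <- cfg$b0_P + cfg$slope_P * Em + SRm

  miss <- function(mat) {
    mat[, -1][stats::runif(n * (length(tt) - 1)) < cfg$missing_rate] <- NA
    mat
  }
  PASo <- miss(PASm); SRo <- miss(SRm); Eo <- miss(Em); Po <- miss(Pm)

  base <- data.frame(participant_id = rep(pid, length(tt)),
                     arm = rep(arm, length(tt)),
                     time = rep(tt, each = n),
                     age = rep(age, length(tt)),
                     gender = rep(gender, length(tt)),
                     education = rep(education, length(tt)),
                     stringsAsFactors = FALSE)
  long <- rbind(
    cbind(base, outcome_name = "E", value = as.vector(Eo)),
    cbind(base, outcome_name = "P", value = as.vector(Po)),
    cbind(base, outcome_name = "SR", value = as.vector(SRo)),
    cbind(base, outcome_name = "PAS", value = as.vector(PASo)))
  rownames(long) <- NULL

  wide <- data.frame(participant_id = pid, arm = arm, age = age,
                     gender = gender, education = education,
                     pas_t0 = PASm[, 1], sr_t0 = SRm[, 1],
                     pas_t2 = PASo[, 3], sr_t3 = SRo[, 4],
                     stringsAsFactors = FALSE)

  nie <- cfg$b_pas_sr * cfg$pas_gain * 2
  te <- cfg$direct_gain * 3 + nie
  list(long = long, wide = wide, items = items,
       truth = list(te = te, nde = cfg$direct_gain * 3, nie = nie,
                    pm = if (te != 0) nie / te else NA_real_,
                    sr_full = SRm, pas_full = PASm),
       config = cfg)
}

#' Inject MCAR missingness into a table
#'
#' Each eligible cell is independently set missing with probability `rate`.
#' Identifier and design columns (`participant_id`, `arm`, `time`,
#' `time_index`, `wave`) are never masked.
#'
#' @param table Data frame.
#' @param rate Missingness probability in [0, 1).
#' @param cols Columns to mask (default: all non-protected columns).
#' @param seed Integer RNG seed.
#' @return The table with missing cells.
#' @export
inject_missingness <- function(table, rate, cols = NULL, seed = 1L) {
  if (rate >= 1 || rate < 0) stop("rate must be in [0, 1)")
  protected <- c("participant_id", "arm", "time", "time_index", "wave")
  if (is.null(cols)) cols <- setdiff(names(table), protected)
  cols <- setdiff(cols, protected)
  set.seed(seed)
  for (cl in cols)
    table[[cl]][stats::runif(nrow(table)) < rate] <- NA
  table
}
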