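# Shared fixture builders. Everything is generated in code; no stored data.

# Paired two-occasion scores engineered to an exact between/within F ratio.
# With subject means m_i and centered within-pair differences d_i,
# MSB = 2 var(m) and MSE = var(d)/2, so F = 4 var(m) / var(d).
make_two_occasion <- function(f_target, n = 200) {
  zs <- function(x) as.numeric(scale(x))  # exact sample mean 0, sd 1
  m <- sqrt(f_target / 4) * zs(seq_len(n))
  d <- zs(rep_len(c(-1, 2, 0, -2, 1), n))
  list(t1 = 10 + m - d / 2, t2 = 10 + m + d / 2)
}

# Two columns with exact sample correlation r and exact unit sample variances.
make_correlated_items <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- as.numeric(scale(z1))
  b <- as.numeric(scale(residuals(lm(z2 ~ a))))
  cbind(item1 = a, item2 = r * a + sqrt(1 - r^2) * b)
}

# Minimal monitoring table with precomputed E/P columns.
make_monitoring <- function(participant_id, time_index, E, P) {
  data.frame(participant_id = participant_id, time_index = time_index,
             E = E, P = P, stringsAsFactors = FALSE)
}

# Saturated trial-dialect stressor report: every life event occurred at the
# top rating, every hassle at maximum frequency.
saturated_respond_report <- function() {
  d <- data.frame(participant_id = "p1", time_index = 0)
  for (j in 1:3) d[[paste0("le_", j)]] <- 4
  for (j in 1:15) d[[paste0("dh_", j)]] <- 3
  d
}

# A respond-dialect report from explicit ratings.
respond_report <- function(le, dh, pid = "p1", t = 0) {
  d <- data.frame(participant_id = pid, time_index = t)
  for (j in seq_along(le)) d[[paste0("le_", j)]] <- le[j]
  for (j in seq_along(dh)) d[[paste0("dh_", j)]] <- dh[j]
  d
}

# Simple linear mediation dataset with planted standardized paths.
make_mediation_data <- function(n, a, b, c_prime = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n)
  y <- c_prime * x + b * m + rnorm(n)
  data.frame(x = x, m = m, y = y)
}

# Two-arm cross-sectional mediation dataset for the counterfactual module.
make_trial_mediation_data <- function(n, a, b, direct = 0, seed = 1) {
  set.seed(seed)
  arm <- rep(c(0, 1), length.out = n)
  age <- rnorm(n, 40, 10)
  m <- 30 + a * arm + 0.05 * age + rnorm(n)
  y <- 5 + direct * arm + b * m + 0.1 * age + rnorm(n)
  data.frame(participant_id = sprintf("s%03d", seq_len(n)),
             arm = arm, age = age, mediator = m, outcome = y)
}
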