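#!/usr/bin/env Rscript
# Prediction of stressor reactivity by baseline resilience factors.
#
# Screens candidate baseline covariates (kept when their univariate p
# against SR(B0-B2) is below 0.2; age and gender always included), then fits
# standardized-beta OLS models of each interval SR score on each battery
# factor, in the full sample and in the high-exposure subsample (top two
# terciles of mean E).

suppressPackageStartupMessages(library(resil))
battery <- read_battery("results/data/battery.csv")
ep <- read.csv("results/data/exposure_symptoms.csv")
sr_all <- read.csv("results/sr_scores.csv")

b0 <- battery[battery$wave == "B0", ]
sr_ref <- merge(b0, sr_all[sr_all$interval == "B0-B2", ], by = "participant_id")

screen <- select_covariates(sr_ref[c("childhood_trauma", "smoking", "income")],
                            sr_ref$sr)
cat("covariate screening (p < 0.2 on SR(B0-B2)):\n")
print(round(screen$screen_pvalues, 3))
cat("selected:", paste(screen$selected, collapse = ", "), "\n\n")

mean_e <- aggregate(E ~ participant_id, data = ep, FUN = mean)
names(mean_e)[2] <- "mean_E"
high <- high_exposure_subset(mean_e)
cat(sprintf("high-exposure subsample: %d of %d participants\n\n",
            length(high), nrow(mean_e)))

predictors <- c("pas_content", "pas_process", "social_support", "recovery")
rows <- list()
for (iv in unique(sr_all$interval)) {
  d <- merge(b0, sr_all[sr_all$interval == iv, ], by = "participant_id")
  for (subset in c("all", "high_exposure")) {
    dd <- if (subset == "all") d else d[d$participant_id %in% high, ]
    for (p in predictors) {
      fit <- fit_sr_regression(dd, p, screen)
      beta <- fit$coefficients[fit$coefficients$term == p, ]
      rows[[length(rows) + 1]] <-
        data.frame(interval = iv, subset = subset, predictor = p,
                   beta = beta$beta, ci_low = beta$ci_low,
                   ci_high = beta$ci_high, p = beta$p,
                   n = fit$n, r2 = fit$r2, adj_r2 = fit$adj_r2)
    }
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/prediction_models.csv", row.names = FALSE)

main <- tab[tab$interval == "B0-B2" & tab$subset == "all", ]
cat("SR(B0-B2), full sample — standardized betas [95% CI]:\n")
for (i in seq_len(nrow(main)))
  cat(sprintf("  %-15s %6.3f [%.3f, %.3f], p = %.2g (n = %d, R2 = %.3f)\n",
              main$predictor[i], main$beta[i], main$ci_low[i],
              main$ci_high[i], main$p[i], main$n[i], main$r2[i]))
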