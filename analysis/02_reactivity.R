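#!/usr/bin/env Rscript
# Exposure scoring and stressor-reactivity (SR) residualization.
#
# Scores exposure E at each analyzed monitoring (T1..T12) as the mean of the
# z-scored life-event and daily-hassle counts, fits the normative E-P line on
# the first three post-baseline monitorings (per-participant averages),
# checks the linearity assumption with a 1-df quadratic likelihood-ratio
# test, quantifies the variance in P explained by E with a random-slope
# mixed model (marginal/conditional R2), and writes interval SR scores.

suppressPackageStartupMessages(library(resil))
monitoring <- read_monitoring("results/data/monitoring.csv")

analysed <- monitoring[monitoring$time_index >= 1, ]  # T0 is acquaintance only
expo <- freshmo_exposure(analysed)
ep <- merge(expo[c("participant_id", "time_index", "E")],
            analysed[c("participant_id", "time_index", "P")],
            by = c("participant_id", "time_index"))

est <- ep[ep$time_index %in% 1:3, ]
agg <- aggregate(cbind(E, P) ~ participant_id, data = est, FUN = mean)
normative <- fit_normative_ols(agg$E, agg$P)
quad <- quadratic_check(agg$E, agg$P)
lmm <- fit_normative_lmm(ep)
r2 <- variance_explained(lmm)

intervals <- list(`B0-B2` = list(times = 1:12, min = 4),
                  `B0-B1` = list(times = 1:6, min = 3),
                  `B1-B2` = list(times = 7:12, min = 3),
                  post_B0_9m = list(times = 1:3, min = 2))
sr_all <- do.call(rbind, lapply(names(intervals), function(nm)
  compute_interval_sr(normative, ep,
                      interval = list(label = nm, times = intervals[[nm]]$times),
                      min_monitorings = intervals[[nm]]$min)))

write.csv(ep, "results/data/exposure_symptoms.csv", row.names = FALSE)
write.csv(sr_all, "results/sr_scores.csv", row.names = FALSE)
jsonlite::write_json(
  list(ols = list(b0 = normative$b0, b1 = normative$b1, r2 = normative$r2),
       quadratic_lrt = quad,
       lmm = list(b0 = lmm$b0, b1 = lmm$b1,
                  r2_marginal = r2$r2_marginal,
                  r2_conditional = r2$r2_conditional)),
  "results/normative_model.json", auto_unbox = TRUE, digits = NA)

print(normative)
cat(sprintf("quadratic term LRT: chi2 = %.2f (df = 1), p = %.3f -> %s\n",
            quad$statistic, quad$p,
            if (quad$p < 0.05) "curvature detected" else "linearity retained"))
cat(sprintf("E explains %.1f%% of variance in P (conditional R2; %.1f%% marginal)\n",
            100 * r2$r2_conditional, 100 * r2$r2_marginal))
cat("SR scores per interval:\n")
print(table(sr_all$interval))
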