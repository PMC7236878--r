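#!/usr/bin/env Rscript
# Stage 4 — the trial statistics on the synthetic cohort.
#
# Reads the cohort written by 01_simulate.R and emits the trial-shaped
# tables: per-outcome baseline/follow-up summaries with the normality-gated
# longitudinal test, the repeatability columns (Spearman rho, Bland-Altman
# limits), the Bonferroni-adjusted correlation matrix, Bland-Altman plot
# data, and the outlier sensitivity analysis of the fat-fraction /
# walk-distance association.

library(dixonmuscle)

out <- "results/run"
cohort <- read_cohort_csv(file.path(out, "cohort.csv"))

summ <- summarize_cohort(cohort)
write.csv(summ, file.path(out, "outcome_summary.csv"), row.names = FALSE)
cat("outcome summary (first rows):\n")
print(summ[1:5, c("outcome", "baseline_median", "test_used", "p_value",
                  "repeat_rho")], digits = 3)

cm <- correlation_matrix(cohort)
write.csv(cm, file.path(out, "correlation_matrix.csv"), row.names = FALSE)
sig <- cm[cm$significant_bonferroni, c("outcome1", "outcome2", "method", "r")]
cat(sprintf("\n%d of %d outcome pairs significant under Bonferroni (m = %d)\n",
            nrow(sig), nrow(cm), unique(cm$m)))

wide <- dixonmuscle:::cohort_wide_baseline(cohort)
sens <- sensitivity_excluding_outlier(wide$value.MRI_FF, wide$value.2MWD)
cat(sprintf("fat fraction vs 2MWD: r = %.3f, r without the most extreme point = %.3f\n",
            sens$r_full, sens$r_excluded))

ba_rows <- list()
for (o in c("2MWD", "10MWR", "4SC", "TUG", "PUL")) {
  sub <- cohort[cohort$outcome == o & cohort$visit == "followup", ]
  d1 <- sub[sub$day == 1, ]; d2 <- sub[sub$day == 2, ]
  ids <- intersect(d1$participant_id, d2$participant_id)
  v1 <- setNames(d1$value, d1$participant_id)[ids]
  v2 <- setNames(d2$value, d2$participant_id)[ids]
  ba <- bland_altman(v1, v2, outcome = o)
  ba_rows[[o]] <- data.frame(outcome = o, mean = ba$means,
                             difference = ba$differences)
  cat(sprintf("%-6s Bland-Altman mean diff %7.3f, LoA [%7.3f, %7.3f]\n",
              o, ba$mean_difference, ba$loa_low, ba$loa_high))
}
write.csv(do.call(rbind, ba_rows), file.path(out, "bland_altman_data.csv"),
          row.names = FALSE)
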