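#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the phantom set used for training and held-out evaluation (ten
# training realizations spanning infiltration fractions 0.1-0.9 and five
# held-out realizations, all at SNR 20) plus a 19-participant synthetic
# cohort, and writes everything under results/run/.

library(dixonmuscle)

out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

train_fracs <- seq(0.1, 0.9, length.out = 10)
for (i in seq_along(train_fracs)) {
  p <- generate_phantom(desk_phantom_params(train_fracs[i], seed = 1000 + i))
  write_dixon_niftis(p$volume, file.path(out, sprintf("train_%02d", i)),
                     p$labels)
}
cat("wrote", length(train_fracs), "training phantoms\n")

test_fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
truth <- data.frame(phantom = seq_along(test_fracs), fraction = NA_real_)
for (i in seq_along(test_fracs)) {
  p <- generate_phantom(desk_phantom_params(test_fracs[i], seed = 7000 + i))
  write_dixon_niftis(p$volume, file.path(out, sprintf("test_%02d", i)),
                     p$labels)
  truth$fraction[i] <- 100 * p$truth$realized_infiltration_fraction
}
write.csv(truth, file.path(out, "test_truth.csv"), row.names = FALSE)
cat("wrote", length(test_fracs), "held-out phantoms; true fat fractions:",
    paste(round(truth$fraction, 1), collapse = " "), "\n")

cohort <- generate_cohort(19, seed = 300)
write_cohort_csv(cohort, file.path(out, "cohort.csv"))
cat("wrote the 19-participant synthetic cohort\n")
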