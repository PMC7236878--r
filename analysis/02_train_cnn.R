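#!/usr/bin/env Rscript
# Stage 2 — build the tissue-signature training set and train the patch CNN.
#
# Reads the training phantoms written by 01_simulate.R, samples 5,000
# class-balanced patches per tissue class, trains for 10 epochs (validation
# profile), and saves the checkpoint plus the per-epoch metrics log.

library(dixonmuscle)

out <- "results/run"
train_files <- list.files(out, "^train_\\d+_labels\\.nii$", full.names = TRUE)
stopifnot(length(train_files) > 0)

pairs <- lapply(train_files, function(lf) {
  prefix <- sub("_labels\\.nii$", "", lf)
  list(volume = read_dixon_niftis(prefix), labels = read_label_nifti(lf))
})
cat("loaded", length(pairs), "training phantoms\n")

patches <- build_training_set(pairs, per_class = 5000, seed = 11)
save_patch_set(patches, file.path(out, "training_patches.rds"))

model <- train_cnn(build_model(4, 4, cnn_config(epochs = 10, seed = 5)),
                   patches)
write.csv(model$history, file.path(out, "training_metrics.csv"),
          row.names = FALSE)
save_model(model, file.path(out, "model.rds"))

h <- tail(model$history, 1)
cat(sprintf("final epoch: loss %.4f, accuracy %.4f, val accuracy %.4f\n",
            h$loss, h$accuracy, h$val_accuracy))
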