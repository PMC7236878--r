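#' Desk-scale phantom parameters
#'
#' A compact profile used throughout examples, vignette and validation runs:
#' 8 slices of 48 x 48 voxels at 5 x 2.5 x 2.5 mm, bone radius 12 mm (3 mm
#' cortical rim), muscle radius 45 mm, subcutaneous rind 10 mm. Keeps full
#' pipeline runs within a few minutes on one CPU while every compartment
#' retains enough voxels for class-balanced sampling.
#'
#' @param infiltration_fraction,seed,snr,... passed to [phantom_params()].
#' @return A `phantom_params` object.
#' @export
desk_phantom_params <- function(infiltration_fraction, seed, snr = 20, ...) {
  phantom_params(grid_shape = c(8L, 48L, 48L), voxel_size_mm = c(5, 2.5, 2.5),
                 bone_radius_mm = 12, bone_rim_mm = 3, muscle_radius_mm = 45,
                 subcut_thickness_mm = 10,
                 infiltration_fraction = infiltration_fraction,
                 snr = snr, seed = seed, ...)
}

#' Demo pipeline configuration
#'
#' A small end-to-end configuration: four training phantoms and two held-out
#' test phantoms, a 1,600-patch training set, a short training schedule, a
#' 19-participant synthetic cohort, and the full statistics stage. Completes
#' in a few minutes on one CPU.
#'
#' @param seed global seed; stage seeds are derived from it.
#' @return A nested configuration list for [run_pipeline()].
#' @export
default_demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(
      grid_shape = c(4L, 40L, 40L), voxel_size_mm = c(5, 2.5, 2.5),
      bone_radius_mm = 12, bone_rim_mm = 3, muscle_radius_mm = 40,
      subcut_thickness_mm = 8, snr = 20,
      train_fractions = c(0.2, 0.4, 0.6, 0.8),
      test_fractions = c(0.3, 0.7)),
    signatures = list(per_class = 400L),
    cnn = list(epochs = 8L, minibatch = 256L),
    quantify = list(fat_weight = 1),
    cohort = list(n_participants = 19L),
    stats = list(alpha = 0.05, nonnormal = c("4SC", "TUG", "10MWR")))
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

validate_config <- function(config) {
  need <- c("seed", "phantom", "signatures", "cnn", "quantify", "cohort", "stats")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing block(s): ", paste(missing, collapse = ", "))
  ph <- config$phantom
  for (f in c("train_fractions", "test_fractions"))
    if (is.null(ph[[f]])) stop("config$phantom$", f, " is required")
  if (is.null(config$signatures$per_class))
    stop("config$signatures$per_class is required")
  invisible(config)
}

config_phantom_params <- function(ph, infiltration_fraction, seed) {
  phantom_params(
    grid_shape = ph$grid_shape %||% c(12L, 64L, 64L),
    voxel_size_mm = ph$voxel_size_mm %||% c(5, 2, 2),
    bone_radius_mm = ph$bone_radius_mm %||% 12,
    bone_rim_mm = ph$bone_rim_mm %||% 3,
    muscle_radius_mm = ph$muscle_radius_mm %||% 45,
    subcut_thickness_mm = ph$subcut_thickness_mm %||% 10,
    infiltration_fraction = infiltration_fraction,
    infiltration_texture = ph$infiltration_texture %||% "uniform",
    snr = ph$snr %||% 20,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes `simulate -> train -> segment -> quantify -> stats` (any prefix
#' of that order) from one configuration, writing all outputs plus a
#' manifest of files, seeds and checksums under `out_dir`. Reruns with the
#' same configuration reproduce identical outputs. A stage failure aborts
#' with the stage name; outputs of completed stages persist.
#'
#' @param config configuration list (see [default_demo_config()]) or a
#'   YAML/JSON path.
#' @param out_dir output directory (created if needed).
#' @param stages stages to run, a prefix of
#'   `c("simulate", "train", "segment", "quantify", "stats")`.
#' @return invisible list with the run's in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "train", "segment",
                                    "quantify", "stats")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  order_all <- c("simulate", "train", "segment", "quantify", "stats")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  if (!identical(stages, order_all[seq_along(stages)]))
    stop("stages must be a prefix of ", paste(order_all, collapse = " -> "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(p) files <<- c(files, p)
  res <- list(config = config)
  seed <- as.integer(config$seed)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      write_manifest(out_dir, config, files, failed_stage = name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    ph <- config$phantom
    mk <- function(fracs, offset, tag) {
      lapply(seq_along(fracs), function(i) {
        p <- generate_phantom(config_phantom_params(ph, fracs[i],
                                                    seed + offset + i))
        prefix <- file.path(out_dir, sprintf("phantom_%s_%02d", tag, i))
        note(write_dixon_niftis(p$volume, prefix, p$labels))
        p
      })
    }
    res$train_phantoms <<- mk(ph$train_fractions, 100L, "train")
    res$test_phantoms <<- mk(ph$test_fractions, 200L, "test")
    res$cohort <<- generate_cohort(config$cohort$n_participants %||% 19L,
                                   seed = seed + 300L)
    note(write_cohort_csv(res$cohort, file.path(out_dir, "cohort.csv")))
  })

  if ("train" %in% stages) run_stage("train", function() {
    ts <- build_training_set(res$train_phantoms,
                             per_class = config$signatures$per_class,
                             seed = seed + 400L)
    note(save_patch_set(ts, file.path(out_dir, "training_patches.rds")))
    cfg <- do.call(cnn_config, c(config$cnn, list(seed = seed + 500L)))
    model <- build_model(4L, 4L, cfg)
    model <- train_cnn(model, ts)
    hist_path <- file.path(out_dir, "training_metrics.csv")
    utils::write.csv(model$history, hist_path, row.names = FALSE)
    note(hist_path)
    note(save_model(model, file.path(out_dir, "model.rds")))
    res$model <<- model
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    res$predicted <<- lapply(seq_along(res$test_phantoms), function(i) {
      pred <- segment_volume(res$model, res$test_phantoms[[i]]$volume)
      prefix <- file.path(out_dir, sprintf("phantom_test_%02d_pred", i))
      p <- paste0(prefix, "_labels.nii")
      RNifti::writeNifti(vol_to_nifti(pred$labels,
                                      res$test_phantoms[[i]]$volume$voxel_size_mm),
                         p, datatype = "int16")
      note(p)
      pred
    })
  })

  if ("quantify" %in% stages) run_stage("quantify", function() {
    w <- config$quantify$fat_weight %||% 1
    res$quant <<- lapply(seq_along(res$predicted), function(i) {
      tp <- res$test_phantoms[[i]]
      q <- tissue_fractions(res$predicted[[i]], tp$params$thigh_slices)
      bc <- body_composition_voxels(res$predicted[[i]], fat_weight = w)
      rec <- list(phantom = i,
                  true_fat_fraction = 100 * tp$truth$realized_infiltration_fraction,
                  estimated_fat_fraction = q$intramuscular_fat_fraction,
                  voxel_counts = as.list(q$voxel_counts),
                  tissue_fractions = as.list(q$tissue_fractions),
                  body_composition = bc)
      p <- file.path(out_dir, sprintf("quant_test_%02d.json", i))
      jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA)
      note(p)
      rec
    })
    ff <- do.call(rbind, lapply(res$quant, function(q)
      data.frame(phantom = q$phantom, true_fat_fraction = q$true_fat_fraction,
                 estimated_fat_fraction = q$estimated_fat_fraction)))
    p <- file.path(out_dir, "fat_fraction_estimates.csv")
    utils::write.csv(ff, p, row.names = FALSE)
    note(p)
  })

  if ("stats" %in% stages) run_stage("stats", function() {
    alpha <- config$stats$alpha %||% 0.05
    summ <- summarize_cohort(res$cohort, alpha = alpha)
    p1 <- file.path(out_dir, "outcome_summary.csv")
    utils::write.csv(summ, p1, row.names = FALSE); note(p1)
    cm <- correlation_matrix(res$cohort,
                             nonnormal = config$stats$nonnormal %||%
                               c("4SC", "TUG", "10MWR"),
                             alpha = alpha)
    p2 <- file.path(out_dir, "correlation_matrix.csv")
    utils::write.csv(cm, p2, row.names = FALSE); note(p2)
    ba_rows <- list()
    for (o in unique(res$cohort$outcome)) {
      sub <- res$cohort[res$cohort$outcome == o & res$cohort$visit == "followup", ]
      d1 <- sub[sub$day == 1L, ]; d2 <- sub[sub$day == 2L, ]
      if (!nrow(d2)) next
      ids <- intersect(d1$participant_id, d2$participant_id)
      v1 <- stats::setNames(d1$value, d1$participant_id)[ids]
      v2 <- stats::setNames(d2$value, d2$participant_id)[ids]
      ba_rows[[o]] <- data.frame(outcome = o, participant_id = ids,
                                 mean = (v1 + v2) / 2, difference = v2 - v1)
    }
    if (length(ba_rows)) {
      p3 <- file.path(out_dir, "bland_altman_data.csv")
      utils::write.csv(do.call(rbind, ba_rows), p3, row.names = FALSE)
      note(p3)
    }
    res$summary <<- summ
    res$correlations <<- cm
  })

  res$manifest <- write_manifest(out_dir, config, files)
  invisible(res)
}

write_manifest <- function(out_dir, config, files, failed_stage = NULL) {
  files <- unique(normalizePath(files, mustWork = FALSE))
  entries <- lapply(files, function(f)
    list(path = basename(f),
         md5 = unname(tools::md5sum(f)),
         bytes = unname(file.size(f))))
  man <- list(seed = config$seed, config = config, files = entries,
              failed_stage = failed_stage,
              n_files = length(entries))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  man
}
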