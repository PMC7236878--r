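roi_counts <- function(labels, roi) {
  stopifnot(inherits(labels, "label_map"))
  d <- dim(labels$labels)
  if (is.null(roi)) roi <- c(1L, d[1])
  roi <- as.integer(roi)
  if (length(roi) != 2L || roi[1] > roi[2] || roi[1] < 1L || roi[2] > d[1])
    stop("roi must be an inclusive slice range within 1..", d[1])
  sub <- labels$labels[roi[1]:roi[2], , , drop = FALSE]
  counts <- tabulate(sub + 1L, nbins = 5L)
  names(counts) <- names(tissue_codes())
  list(counts = counts, roi = roi)
}

#' Per-tissue voxel counts and fractions over a slice ROI
#'
#' Counts voxels of each tissue class over the given slice range and derives
#' per-class fractions with in-body voxels (classes 1-4) as denominator;
#' background air is excluded. Also computes the intramuscular fat fraction
#' (see [intramuscular_fat_fraction()]) and its complementary muscle
#' fraction.
#'
#' @param labels a `label_map` (ground truth or predicted).
#' @param roi inclusive slice index range `c(lo, hi)`; `NULL` for all slices.
#' @return A `quant_result`: list with `roi`, `voxel_counts`,
#'   `tissue_fractions` (classes 1-4, summing to 1),
#'   `intramuscular_fat_fraction` and `muscle_fraction` (percent, summing to
#'   100), `total_fat_voxels`, `total_muscle_voxels`.
#' @export
tissue_fractions <- function(labels, roi = NULL) {
  rc <- roi_counts(labels, roi)
  counts <- rc$counts
  in_body <- sum(counts[2:5])
  if (in_body == 0) stop("ROI contains no in-body voxels (all background)")
  fr <- counts[2:5] / in_body
  imff <- if (counts[["healthy_muscle"]] + counts[["fat_infiltrated_muscle"]] > 0)
    intramuscular_fat_fraction(labels, rc$roi) else NA_real_
  structure(list(
    roi = rc$roi, voxel_counts = counts, tissue_fractions = fr,
    intramuscular_fat_fraction = imff,
    muscle_fraction = if (is.na(imff)) NA_real_ else 100 - imff,
    total_fat_voxels = unname(counts[["subcutaneous_fat"]] +
                              counts[["fat_infiltrated_muscle"]]),
    total_muscle_voxels = unname(counts[["healthy_muscle"]])),
    class = "quant_result")
}

#' Intramuscular fat fraction
#'
#' Percentage of muscle-compartment voxels classified as fat-infiltrated:
#' `100 * n(fat-infiltrated muscle) / (n(healthy muscle) + n(fat-infiltrated
#' muscle))` over the ROI. Bone and subcutaneous fat never enter numerator or
#' denominator; including them would make subjects with more subcutaneous fat
#' appear to have lower intramuscular fat at identical infiltration.
#'
#' @inheritParams tissue_fractions
#' @return Fat fraction in percent.
#' @export
intramuscular_fat_fraction <- function(labels, roi = NULL) {
  rc <- roi_counts(labels, roi)
  hm <- rc$counts[["healthy_muscle"]]
  fi <- rc$counts[["fat_infiltrated_muscle"]]
  if (hm + fi == 0) stop("ROI contains no muscle voxels")
  100 * fi / (hm + fi)
}

#' Whole-volume fat and muscle voxel totals
#'
#' Voxel-count body-composition summary over the full volume (not the thigh
#' ROI), for comparison against absorptiometry-style measures:
#' `total_fat_voxels = n(subcutaneous fat) + w * n(fat-infiltrated muscle)`
#' and `total_muscle_voxels = n(healthy muscle)`. The fat content `w` of an
#' infiltrated-muscle voxel is configurable and reported alongside the
#' counts.
#'
#' @param labels a `label_map`.
#' @param fat_weight w in [0, 1]; default 1 counts infiltrated muscle fully
#'   toward body fat.
#' @return list with `total_fat_voxels`, `total_muscle_voxels`, `fat_weight`.
#' @export
body_composition_voxels <- function(labels, fat_weight = 1) {
  if (fat_weight < 0 || fat_weight > 1) stop("fat_weight must be in [0, 1]")
  rc <- roi_counts(labels, NULL)
  list(total_fat_voxels = unname(rc$counts[["subcutaneous_fat"]] +
                                 fat_weight * rc$counts[["fat_infiltrated_muscle"]]),
       total_muscle_voxels = unname(rc$counts[["healthy_muscle"]]),
       fat_weight = fat_weight)
}

#' Append a measured fat fraction to a cohort table
#'
#' Adds (or replaces) the `MRI_FF` outcome row of one participant/visit with
#' a value measured by the imaging pipeline, keeping the long-table layout.
#'
#' @param cohort a `cohort_table`.
#' @param participant_id,visit row identity (`visit` in
#'   `baseline`/`followup`).
#' @param value intramuscular fat fraction in percent.
#' @return The updated `cohort_table`.
#' @export
append_fat_fraction <- function(cohort, participant_id, visit, value) {
  stopifnot(visit %in% c("baseline", "followup"),
            value >= 0, value <= 100)
  hit <- cohort$participant_id == participant_id & cohort$visit == visit &
    cohort$day == 1L & cohort$outcome == "MRI_FF"
  if (any(hit)) {
    cohort$value[hit] <- value
    return(cohort)
  }
  row <- cohort[1, ]
  demo <- cohort[match(participant_id, cohort$participant_id), ]
  row$participant_id <- participant_id
  row$visit <- visit; row$day <- 1L
  row$outcome <- "MRI_FF"; row$value <- value
  for (col in intersect(c("sex", "age_years", "bmi", "ck_UL",
                          "genotype_class"), names(cohort)))
    row[[col]] <- demo[[col]]
  out <- rbind(cohort, row)
  class(out) <- class(cohort)
  out
}

#' Dice overlap coefficient of one tissue class
#'
#' `2 |A n B| / (|A| + |B|)` between a predicted and a reference label map.
#'
#' @param pred,truth `label_map`s (or integer arrays) of identical shape.
#' @param class tissue class code.
#' @return Dice coefficient in [0, 1]; `NaN` if the class is absent from
#'   both.
#' @export
dice_coefficient <- function(pred, truth, class) {
  if (inherits(pred, "label_map")) pred <- pred$labels
  if (inherits(truth, "label_map")) truth <- truth$labels
  stopifnot(identical(dim(pred), dim(truth)))
  a <- pred == class; b <- truth == class
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' @exportS3Method base::print
print.quant_result <- function(x, ...) {
  cat("<quant_result> slices", x$roi[1], "-", x$roi[2], "\n")
  print(x$voxel_counts)
  cat(sprintf("  intramuscular fat fraction: %.2f%% (muscle %.2f%%)\n",
              x$intramuscular_fat_fraction, x$muscle_fraction))
  invisible(x)
}
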