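# Volumes are held internally as (z, y, x) arrays; on disk they follow the
# NIfTI (x, y, z) convention with voxel spacing in the pixdim field.
vol_to_nifti <- function(arr, voxel_size_mm) {
  a <- aperm(arr, c(3, 2, 1))
  RNifti::asNifti(a, list(pixdim = c(0, voxel_size_mm[3], voxel_size_mm[2],
                                     voxel_size_mm[1], 0, 0, 0, 0)))
}

nifti_to_vol <- function(img) {
  list(arr = aperm(as.array(img), c(3, 2, 1)),
       voxel_size_mm = rev(RNifti::pixdim(img)[1:3]))
}

dixon_suffixes <- function() {
  c(in_phase = "_ip", opposed_phase = "_op", water = "_water", fat = "_fat")
}

#' Write a Dixon volume (and optional labels) as NIfTI files
#'
#' Four channel files with fixed suffixes `_ip`, `_op`, `_water`, `_fat`
#' (plus `_labels` when a label map is given); voxel spacing is encoded in
#' the NIfTI header. Values are stored as doubles so the round trip is
#' bit-exact.
#'
#' @param volume a `dixon_volume`.
#' @param prefix output path prefix (directory must exist).
#' @param labels optional `label_map`.
#' @return invisible character vector of the files written.
#' @export
write_dixon_niftis <- function(volume, prefix, labels = NULL) {
  stopifnot(inherits(volume, "dixon_volume"))
  sfx <- dixon_suffixes()
  paths <- character(0)
  for (ch in names(sfx)) {
    p <- paste0(prefix, sfx[[ch]], ".nii")
    RNifti::writeNifti(vol_to_nifti(volume[[ch]], volume$voxel_size_mm), p,
                       datatype = "double")
    paths <- c(paths, p)
  }
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_map"))
    p <- paste0(prefix, "_labels.nii")
    RNifti::writeNifti(vol_to_nifti(labels$labels, volume$voxel_size_mm), p,
                       datatype = "int16")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read four co-registered Dixon channel NIfTIs into a volume
#'
#' Channel identity is fixed by the filename suffix convention of
#' [write_dixon_niftis()] (`_ip`, `_op`, `_water`, `_fat`), not by header
#' inspection. All four files must agree in dimensions and voxel spacing.
#'
#' @param paths character vector of the four channel file paths, or a single
#'   prefix from which the suffixed paths are derived.
#' @param thigh_slices optional inclusive slice range; defaults to all.
#' @return A `dixon_volume`.
#' @export
read_dixon_niftis <- function(paths, thigh_slices = NULL) {
  sfx <- dixon_suffixes()
  if (length(paths) == 1L && !grepl("\\.nii(\\.gz)?$", paths))
    paths <- paste0(paths, sfx, ".nii")
  if (length(paths) != 4L) stop("expected four channel files, got ", length(paths))
  chan_of <- function(p) {
    base <- sub("\\.nii(\\.gz)?$", "", basename(p))
    hit <- names(sfx)[vapply(sfx, function(s) endsWith(base, s), logical(1))]
    if (length(hit) != 1L)
      stop("cannot identify the channel of '", p,
           "' from its suffix (expected one of ",
           paste(sfx, collapse = ", "), ")")
    hit
  }
  chans <- vapply(paths, chan_of, character(1))
  if (anyDuplicated(chans)) stop("duplicate channel suffixes among inputs")
  missing <- setdiff(names(sfx), chans)
  if (length(missing)) stop("missing channel file(s): ", paste(missing, collapse = ", "))
  vols <- lapply(paths, function(p) nifti_to_vol(RNifti::readNifti(p)))
  names(vols) <- chans
  ref <- vols[[1]]
  for (k in seq_along(vols)[-1]) {
    if (!identical(dim(vols[[k]]$arr), dim(ref$arr)))
      stop("shape mismatch between '", paths[1], "' and '", paths[k], "'")
    if (!isTRUE(all.equal(vols[[k]]$voxel_size_mm, ref$voxel_size_mm)))
      stop("voxel-size mismatch between '", paths[1], "' and '", paths[k], "'")
  }
  d <- dim(ref$arr)
  if (is.null(thigh_slices)) thigh_slices <- c(1L, d[1])
  structure(list(in_phase = vols$in_phase$arr,
                 opposed_phase = vols$opposed_phase$arr,
                 water = vols$water$arr, fat = vols$fat$arr,
                 voxel_size_mm = ref$voxel_size_mm,
                 thigh_slices = as.integer(thigh_slices)),
            class = "dixon_volume")
}

#' Read a predicted or ground-truth label NIfTI
#' @param path a `_labels.nii` file.
#' @return A `label_map`.
#' @export
read_label_nifti <- function(path) {
  v <- nifti_to_vol(RNifti::readNifti(path))
  structure(list(labels = array(as.integer(v$arr), dim = dim(v$arr)),
                 code_names = tissue_codes()),
            class = "label_map")
}

#' Write / read the long-format cohort CSV
#'
#' The on-disk format is the five-column long table
#' `participant_id,visit,day,outcome,value`; demographic columns present in
#' memory are written to a sidecar `<path>_demographics.csv`.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return invisible path(s) written.
#' @export
write_cohort_csv <- function(cohort, path) {
  core <- cohort[, c("participant_id", "visit", "day", "outcome", "value")]
  utils::write.csv(core, path, row.names = FALSE, quote = FALSE)
  paths <- path
  demo_cols <- intersect(c("sex", "age_years", "bmi", "ck_UL", "genotype_class"),
                         names(cohort))
  if (length(demo_cols)) {
    demo <- unique(cohort[, c("participant_id", demo_cols)])
    p2 <- sub("\\.csv$", "_demographics.csv", path)
    utils::write.csv(demo, p2, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "visit", "day", "outcome", "value")
  if (!all(need %in% names(tab)))
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  demo_path <- sub("\\.csv$", "_demographics.csv", path)
  if (file.exists(demo_path)) {
    demo <- utils::read.csv(demo_path, stringsAsFactors = FALSE)
    tab <- merge(tab, demo, by = "participant_id", sort = FALSE)
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Save / load a patch set archive
#'
#' A single binary archive of the arrays plus a JSON sidecar recording the
#' normalization statistics and sampling seed.
#'
#' @param ps a `patch_set`.
#' @param path archive path (`.rds`).
#' @return invisible paths written / the loaded `patch_set`.
#' @export
save_patch_set <- function(ps, path) {
  stopifnot(inherits(ps, "patch_set"))
  saveRDS(ps, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(n = nrow(ps$patches),
                            normalization_stats = ps$normalization_stats,
                            seed = ps$seed),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname save_patch_set
#' @export
load_patch_set <- function(path) {
  ps <- readRDS(path)
  stopifnot(inherits(ps, "patch_set"))
  ps
}

#' Save / load a trained model checkpoint
#'
#' Binary checkpoint plus a JSON sidecar with the config snapshot (including
#' recorded overrides) and the class-code mapping.
#'
#' @param model an `mpdl_cnn`.
#' @param path checkpoint path (`.rds`).
#' @return invisible paths written / the loaded model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mpdl_cnn"))
  saveRDS(model, path)
  cfg <- model$config
  side <- paste0(path, ".json")
  jsonlite::write_json(list(config = unclass(cfg),
                            class_codes = model$class_codes,
                            trained = model$trained,
                            epochs_run = if (is.null(model$history)) 0L
                                         else nrow(model$history)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "mpdl_cnn"))
  m
}
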