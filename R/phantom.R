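#' Phantom generation parameters
#'
#' Bundles the geometry, tissue-contrast and noise settings of the synthetic
#' thigh phantom. Each axial slice holds a concentric cross-section: a bone
#' core (cortical rim around a fatty marrow centre), a muscle annulus of which
#' a controllable fraction is fat-infiltrated, a subcutaneous fat rind, and
#' air background. Intensities are in arbitrary units; downstream signature
#' extraction must not depend on absolute scale.
#'
#' @param grid_shape integer (z, y, x) voxel counts.
#' @param voxel_size_mm numeric (dz, dy, dx) spacing in mm; the 5 mm default
#'   slice thickness matches a typical whole-body Dixon protocol.
#' @param bone_radius_mm radius of the bone core (cortical rim + marrow).
#' @param bone_rim_mm thickness of the low-signal cortical rim within the bone
#'   core; the remainder is fat-like marrow. Both carry the bone label.
#' @param muscle_radius_mm outer radius of the muscle annulus.
#' @param subcut_thickness_mm thickness of the subcutaneous fat rind.
#' @param infiltration_fraction target fraction of muscle-compartment voxels
#'   converted to fat-infiltrated muscle, in [0, 1].
#' @param infiltration_texture `"uniform"` (independent random voxels; realized
#'   fraction exact to one voxel) or `"clustered"` (thresholded smoothed noise,
#'   spatially correlated as in dystrophic muscle).
#' @param infiltration_mixing fat content of an infiltrated-muscle voxel on the
#'   water-to-fat axis, in (0, 1); 0 would be pure muscle contrast, 1 pure fat.
#' @param snr signal-to-noise ratio (mean in-body in-phase intensity divided by
#'   the per-channel noise SD); `Inf` for a noiseless phantom.
#' @param noise_model `"rician"` (Gaussian noise on water/fat before the Dixon
#'   combination, magnitudes taken afterwards) or `"gaussian"` (bias-free;
#'   negative values clipped at zero).
#' @param seed integer RNG seed; the phantom is bit-reproducible from it.
#' @param thigh_slices inclusive slice index range treated as thigh ROI;
#'   defaults to all slices.
#' @return A `phantom_params` list, validated.
#' @export
phantom_params <- function(grid_shape = c(12L, 64L, 64L),
                           voxel_size_mm = c(5, 2, 2),
                           bone_radius_mm = 12,
                           bone_rim_mm = 3,
                           muscle_radius_mm = 45,
                           subcut_thickness_mm = 10,
                           infiltration_fraction = 0.3,
                           infiltration_texture = c("uniform", "clustered"),
                           infiltration_mixing = 0.6,
                           snr = Inf,
                           noise_model = c("rician", "gaussian"),
                           seed = 1L,
                           thigh_slices = NULL) {
  infiltration_texture <- match.arg(infiltration_texture)
  noise_model <- match.arg(noise_model)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be three positive integers (z, y, x)")
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive spacings (dz, dy, dx)")
  if (bone_radius_mm <= 0 || muscle_radius_mm <= 0 || subcut_thickness_mm < 0)
    stop("radii must be positive and subcut_thickness_mm nonnegative")
  if (bone_radius_mm >= muscle_radius_mm)
    stop("bone_radius_mm must be smaller than muscle_radius_mm")
  if (bone_rim_mm <= 0 || bone_rim_mm >= bone_radius_mm)
    stop("bone_rim_mm must lie strictly between 0 and bone_radius_mm")
  if (infiltration_fraction < 0 || infiltration_fraction > 1)
    stop("infiltration_fraction must be in [0, 1]")
  if (infiltration_mixing <= 0 || infiltration_mixing >= 1)
    stop("infiltration_mixing must be in (0, 1)")
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be positive or Inf")
  body_radius <- muscle_radius_mm + subcut_thickness_mm
  half_extent <- c(grid_shape[2] * voxel_size_mm[2],
                   grid_shape[3] * voxel_size_mm[3]) / 2
  if (any(body_radius > half_extent))
    stop("grid too small: muscle_radius_mm + subcut_thickness_mm (", body_radius,
         " mm) exceeds the in-plane half-extent (", min(half_extent), " mm)")
  if (is.null(thigh_slices)) thigh_slices <- c(1L, grid_shape[1])
  thigh_slices <- as.integer(thigh_slices)
  if (length(thigh_slices) != 2L || thigh_slices[1] < 1L ||
      thigh_slices[2] > grid_shape[1] || thigh_slices[1] > thigh_slices[2])
    stop("thigh_slices must be an inclusive in-range slice index pair")
  structure(list(
    grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
    bone_radius_mm = bone_radius_mm, bone_rim_mm = bone_rim_mm,
    muscle_radius_mm = muscle_radius_mm,
    subcut_thickness_mm = subcut_thickness_mm,
    infiltration_fraction = infiltration_fraction,
    infiltration_texture = infiltration_texture,
    infiltration_mixing = infiltration_mixing,
    snr = snr, noise_model = noise_model, seed = as.integer(seed),
    thigh_slices = thigh_slices
  ), class = "phantom_params")
}

#' Tissue class codes of the label map
#'
#' 0 background (air), 1 healthy muscle, 2 subcutaneous fat,
#' 3 fat-infiltrated muscle, 4 bone (cortical rim and marrow).
#' @return Named integer vector.
#' @export
tissue_codes <- function() {
  c(background = 0L, healthy_muscle = 1L, subcutaneous_fat = 2L,
    fat_infiltrated_muscle = 3L, bone = 4L)
}

# Mean water/fat channel intensities (arbitrary units) per rendering class.
# Fat-infiltrated muscle interpolates between muscle and fat contrast by the
# mixing parameter m: W = Wm - m*(Wm - Wf), F = Fm + m*(Ff - Fm).
phantom_class_means <- function(mixing) {
  m <- rbind(
    healthy_muscle   = c(water = 0.90, fat = 0.08),
    subcutaneous_fat = c(water = 0.08, fat = 0.90),
    bone_rim         = c(water = 0.04, fat = 0.04),
    bone_marrow      = c(water = 0.12, fat = 0.80))
  infil <- c(water = 0.90 - mixing * (0.90 - 0.08),
             fat   = 0.08 + mixing * (0.90 - 0.08))
  rbind(m, fat_infiltrated_muscle = infil)
}

#' Two-point Dixon forward model
#'
#' Combines water and fat signal into the in-phase and opposed-phase echoes:
#' `in_phase = water + fat`, `opposed_phase = |water - fat|` (magnitude
#' reconstruction; only two echoes are acquired, so the opposed-phase sign is
#' not resolvable).
#'
#' @param water,fat nonnegative numeric arrays of identical shape.
#' @return list with `in_phase` and `opposed_phase`.
#' @export
dixon_forward <- function(water, fat) {
  if (!identical(dim(water), dim(fat)) && length(water) != length(fat))
    stop("water and fat must share one shape")
  if (any(water < 0) || any(fat < 0))
    stop("water and fat intensities must be nonnegative")
  list(in_phase = water + fat, opposed_phase = abs(water - fat))
}

# Separable in-plane Gaussian smoothing of one slice (matrix), used for the
# clustered infiltration texture and for body masking.
gauss_smooth_slice <- function(m, sd_vox) {
  if (sd_vox <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_vox))
  k <- stats::dnorm(-half:half, sd = sd_vox)
  k <- k / sum(k)
  smooth_dim <- function(x, n) {
    # replicate-padded 1-D convolution along rows
    idx <- pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
    K <- matrix(0, n, n)
    for (j in seq_along(k)) {
      rows <- idx[seq_len(n) + j - 1L]
      K[cbind(seq_len(n), rows)] <- K[cbind(seq_len(n), rows)] + k[j]
    }
    K %*% x
  }
  t(smooth_dim(t(smooth_dim(m, nrow(m))), ncol(m)))
}

#' Generate a synthetic Dixon thigh phantom
#'
#' Renders the concentric-cylinder geometry described in [phantom_params()],
#' relabels the requested fraction of muscle voxels as fat-infiltrated,
#' synthesizes the water/fat channels from per-class mean intensities, derives
#' in-phase and opposed-phase by the Dixon forward model, and finally adds
#' channel noise at the requested SNR. Fully reproducible from `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @return list with elements
#'   `volume` (a `dixon_volume`: `in_phase`, `opposed_phase`, `water`, `fat`
#'   arrays, `voxel_size_mm`, `thigh_slices`),
#'   `labels` (a `label_map`: integer array plus `code_names`),
#'   `params`, and `truth` (generator records: realized infiltration fraction,
#'   per-class voxel counts, analytic compartment volumes in mm^3, class means,
#'   noise SD).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  nz <- p$grid_shape[1]; ny <- p$grid_shape[2]; nx <- p$grid_shape[3]
  dy <- p$voxel_size_mm[2]; dx <- p$voxel_size_mm[3]

  # voxel-centre radii from the in-plane grid centre, one representative slice
  yc <- (seq_len(ny) - 0.5) * dy - ny * dy / 2
  xc <- (seq_len(nx) - 0.5) * dx - nx * dx / 2
  r <- sqrt(outer(yc^2, xc^2, "+"))

  # rendering classes: 0 bg, 1 muscle, 2 subcut, 3 infil, 4 rim, 5 marrow
  slice_cls <- matrix(0L, ny, nx)
  slice_cls[r <= p$muscle_radius_mm + p$subcut_thickness_mm] <- 2L
  slice_cls[r <= p$muscle_radius_mm] <- 1L
  slice_cls[r <= p$bone_radius_mm] <- 4L
  slice_cls[r <= p$bone_radius_mm - p$bone_rim_mm] <- 5L

  cls <- array(rep(slice_cls, times = nz), dim = c(ny, nx, nz))
  cls <- aperm(cls, c(3, 1, 2))                       # (z, y, x)

  set.seed(p$seed)
  muscle_idx <- which(cls == 1L)
  n_muscle <- length(muscle_idx)
  n_infil <- round(p$infiltration_fraction * n_muscle)
  if (n_infil > 0) {
    if (p$infiltration_texture == "uniform") {
      take <- sample(muscle_idx, n_infil)
    } else {
      noise <- array(stats::rnorm(nz * ny * nx), dim = c(nz, ny, nx))
      for (z in seq_len(nz))
        noise[z, , ] <- gauss_smooth_slice(noise[z, , ], sd_vox = 2)
      vals <- noise[muscle_idx]
      take <- muscle_idx[order(vals, decreasing = TRUE)[seq_len(n_infil)]]
    }
    cls[take] <- 3L
  } else if (p$infiltration_texture == "clustered") {
    # keep the RNG stream aligned across textures for a given seed
    invisible(stats::rnorm(nz * ny * nx))
  }

  means <- phantom_class_means(p$infiltration_mixing)
  wmap <- c(0, means["healthy_muscle", "water"], means["subcutaneous_fat", "water"],
            means["fat_infiltrated_muscle", "water"], means["bone_rim", "water"],
            means["bone_marrow", "water"])
  fmap <- c(0, means["healthy_muscle", "fat"], means["subcutaneous_fat", "fat"],
            means["fat_infiltrated_muscle", "fat"], means["bone_rim", "fat"],
            means["bone_marrow", "fat"])
  water <- array(wmap[cls + 1L], dim = dim(cls))
  fat <- array(fmap[cls + 1L], dim = dim(cls))

  clean <- dixon_forward(water, fat)
  in_body <- cls > 0L
  sigma <- 0
  if (is.finite(p$snr)) {
    sigma <- mean(clean$in_phase[in_body]) / p$snr
    ew <- array(stats::rnorm(length(water), sd = sigma), dim = dim(water))
    ef <- array(stats::rnorm(length(fat), sd = sigma), dim = dim(fat))
    if (p$noise_model == "rician") {
      wn <- water + ew; fn <- fat + ef
      in_phase <- abs(wn + fn); opposed <- abs(wn - fn)
      water <- abs(wn); fat <- abs(fn)
    } else {
      water <- pmax(water + ew, 0); fat <- pmax(fat + ef, 0)
      in_phase <- water + fat; opposed <- abs(water - fat)
    }
  } else {
    in_phase <- clean$in_phase; opposed <- clean$opposed_phase
  }

  labels <- cls
  labels[labels == 5L] <- 4L
  label_map <- structure(list(labels = labels, code_names = tissue_codes()),
                         class = "label_map")
  volume <- structure(list(
    in_phase = in_phase, opposed_phase = opposed, water = water, fat = fat,
    voxel_size_mm = p$voxel_size_mm, thigh_slices = p$thigh_slices
  ), class = "dixon_volume")

  vox_mm3 <- prod(p$voxel_size_mm)
  slice_area <- function(r_out, r_in = 0) pi * (r_out^2 - r_in^2)
  h <- nz * p$voxel_size_mm[1]
  counts <- tabulate(labels + 1L, nbins = 5L)
  names(counts) <- names(tissue_codes())
  truth <- list(
    realized_infiltration_fraction = if (n_muscle > 0) n_infil / n_muscle else NA_real_,
    n_muscle_compartment = n_muscle,
    voxel_counts = counts,
    fat_volume_mm3_voxel = (counts[["subcutaneous_fat"]] +
                            counts[["fat_infiltrated_muscle"]]) * vox_mm3,
    analytic_volumes_mm3 = c(
      bone = slice_area(p$bone_radius_mm) * h,
      muscle_compartment = slice_area(p$muscle_radius_mm, p$bone_radius_mm) * h,
      subcutaneous_fat = slice_area(p$muscle_radius_mm + p$subcut_thickness_mm,
                                    p$muscle_radius_mm) * h,
      fat_total = (slice_area(p$muscle_radius_mm + p$subcut_thickness_mm,
                              p$muscle_radius_mm) +
                   p$infiltration_fraction *
                     slice_area(p$muscle_radius_mm, p$bone_radius_mm)) * h),
    class_means = means,
    noise_sd = sigma)

  list(volume = volume, labels = label_map, params = p, truth = truth)
}

#' @exportS3Method base::print
print.dixon_volume <- function(x, ...) {
  d <- dim(x$in_phase)
  cat("<dixon_volume> ", paste(d, collapse = " x "),
      " voxels (z y x), spacing ", paste(x$voxel_size_mm, collapse = "/"),
      " mm, thigh slices ", x$thigh_slices[1], "-", x$thigh_slices[2], "\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "), " voxels\n", sep = "")
  tab <- tabulate(x$labels + 1L, nbins = 5L)
  names(tab) <- names(x$code_names)
  print(tab)
  invisible(x)
}
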