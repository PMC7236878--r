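# Channel order of the tissue-signature vector; fixed across the package.
signature_channels <- function() c("in_phase", "opposed_phase", "water", "fat")

#' Body mask of a Dixon volume
#'
#' In-body voxels must exceed both an in-plane Gaussian-smoothed in-phase
#' threshold (a fraction of the smoothed image's 99th percentile, which
#' rejects isolated bright noise voxels in air) and a low raw-intensity
#' threshold (which rejects the ring of air voxels bordering the body whose
#' smoothed value is inflated by bright neighbors). Low-signal cortical bone,
#' abutting bright marrow and muscle, stays inside. An all-zero volume yields
#' an empty mask.
#'
#' @param volume a `dixon_volume`.
#' @param threshold_frac smoothed-image threshold as a fraction of the 99th
#'   percentile of the smoothed in-phase image.
#' @param raw_frac raw in-phase threshold as a fraction of the same
#'   percentile.
#' @param smooth_sd_vox in-plane Gaussian SD in voxels.
#' @return logical array, `TRUE` for in-body voxels.
#' @export
body_mask <- function(volume, threshold_frac = 0.15, raw_frac = 0.05,
                      smooth_sd_vox = 1) {
  ip <- volume$in_phase
  sm <- ip
  for (z in seq_len(dim(ip)[1]))
    sm[z, , ] <- gauss_smooth_slice(ip[z, , ], smooth_sd_vox)
  q <- stats::quantile(sm, 0.99, names = FALSE)
  (sm > threshold_frac * q) & (ip > raw_frac * q)
}

#' Per-volume signature normalization statistics
#'
#' Each channel is scaled by its 99th-percentile intensity over in-body
#' voxels, making signatures invariant to the arbitrary global intensity
#' scale of scanner or phantom data. Channels that are everywhere zero get a
#' unit scale.
#'
#' @param volume a `dixon_volume`.
#' @param mask optional precomputed [body_mask()].
#' @return list with `scale` (named per-channel divisors) and `mask`.
#' @export
signature_stats <- function(volume, mask = NULL) {
  if (is.null(mask)) mask <- body_mask(volume)
  ch <- signature_channels()
  sc <- vapply(ch, function(nm) {
    v <- volume[[nm]][mask]
    if (length(v) == 0) return(1)
    q <- stats::quantile(v, 0.99, names = FALSE)
    if (q <= 0) 1 else q
  }, numeric(1))
  list(scale = sc, mask = mask)
}

check_coord <- function(volume, coord) {
  d <- dim(volume$in_phase)
  if (length(coord) != 3L || any(coord < 1) || any(coord > d))
    stop("coord (z, y, x) = (", paste(coord, collapse = ", "),
         ") is outside the volume of shape ", paste(d, collapse = " x "))
  as.integer(coord)
}

#' Extract a tissue-signature vector at one voxel
#'
#' Returns the normalized intensities of the four co-registered Dixon
#' channels at a voxel, in the fixed order in-phase, opposed-phase, water,
#' fat. This per-voxel vector of gray-level intensities across channels is
#' the multiparametric tissue signature the classifier consumes.
#'
#' @param volume a `dixon_volume`.
#' @param coord integer (z, y, x) voxel coordinate.
#' @param stats optional precomputed [signature_stats()].
#' @return named numeric vector of length 4.
#' @export
extract_signature <- function(volume, coord, stats = NULL) {
  coord <- check_coord(volume, coord)
  if (is.null(stats)) stats <- signature_stats(volume)
  ch <- signature_channels()
  vapply(ch, function(nm)
    volume[[nm]][coord[1], coord[2], coord[3]] / stats$scale[[nm]],
    numeric(1))
}

# Vectorized in-plane 5x5 patch extraction with replicate padding at slice
# edges. coords: n x 3 matrix (z, y, x). Returns an n x 100 matrix whose
# columns are ordered x-offset fastest, then y-offset, then channel -- the
# flat layout the CNN's im2col plans assume.
extract_patches_matrix <- function(volume, coords, stats) {
  ch <- signature_channels()
  d <- dim(volume$in_phase)
  n <- nrow(coords)
  out <- matrix(0, n, 25L * length(ch))
  for (z in unique(coords[, 1])) {
    sel <- which(coords[, 1] == z)
    ys <- coords[sel, 2]; xs <- coords[sel, 3]
    for (ci in seq_along(ch)) {
      sl <- volume[[ch[ci]]][z, , ] / stats$scale[[ch[ci]]]
      for (j in 1:5) {
        yy <- pmin(pmax(ys + j - 3L, 1L), d[2])
        for (i in 1:5) {
          xx <- pmin(pmax(xs + i - 3L, 1L), d[3])
          out[sel, i + 5L * (j - 1L) + 25L * (ci - 1L)] <- sl[cbind(yy, xx)]
        }
      }
    }
  }
  out
}

#' Extract a 5 x 5 x N signature patch at one voxel
#'
#' The in-plane 5 x 5 neighborhood of the voxel across all N = 4 channels,
#' normalized per volume. Neighbors falling outside the slice are filled by
#' edge replication so border patches do not contain artificial air-like
#' signatures. The patch's central value equals [extract_signature()] at the
#' same coordinate.
#'
#' @inheritParams extract_signature
#' @return numeric array of dim `c(5, 5, 4)`, indexed (y-offset, x-offset,
#'   channel).
#' @export
extract_patch <- function(volume, coord, stats = NULL) {
  coord <- check_coord(volume, coord)
  if (is.null(stats)) stats <- signature_stats(volume)
  flat <- extract_patches_matrix(volume, matrix(coord, 1), stats)
  # flat columns: x fastest, then y, then channel -> array (x, y, c), then
  # swap to (y, x, c)
  a <- array(flat[1, ], dim = c(5, 5, 4))
  a <- aperm(a, c(2, 1, 3))
  dimnames(a) <- list(NULL, NULL, signature_channels())
  a
}

#' Assemble a class-balanced labeled training set of signature patches
#'
#' Samples `per_class` patch centers uniformly at random from the voxels of
#' each tissue class 1-4 pooled over all supplied (volume, label map) pairs;
#' background is never sampled. The returned set is shuffled and carries the
#' per-volume normalization statistics used.
#'
#' @param pairs list of `list(volume =, labels =)` pairs (e.g. outputs of
#'   [generate_phantom()]).
#' @param per_class patches to draw per tissue class (>= 1).
#' @param seed integer RNG seed.
#' @return A `patch_set`: list with `patches` (n x 100 matrix, flat 5x5x4
#'   layout), `centers` (n x 4 matrix: pair index, z, y, x), `labels`
#'   (integer, in 1-4), `normalization_stats` (per-pair channel scales),
#'   `seed`.
#' @export
build_training_set <- function(pairs, per_class, seed = 1L) {
  if (per_class < 1) stop("per_class must be >= 1")
  if (!length(pairs)) stop("no (volume, labels) pairs supplied")
  classes <- 1:4
  avail <- lapply(pairs, function(p) {
    stopifnot(inherits(p$volume, "dixon_volume"), inherits(p$labels, "label_map"))
    if (!identical(dim(p$volume$in_phase), dim(p$labels$labels)))
      stop("label map not aligned to its volume")
    p$labels$labels
  })
  set.seed(as.integer(seed))
  # pooled candidate voxel list per class: (pair, linear index)
  picks <- vector("list", length(classes))
  for (k in classes) {
    cand <- do.call(rbind, lapply(seq_along(avail), function(i) {
      idx <- which(avail[[i]] == k)
      if (length(idx)) cbind(pair = i, lin = idx) else NULL
    }))
    n_av <- if (is.null(cand)) 0L else nrow(cand)
    if (n_av < per_class)
      stop("class ", k, " (", names(tissue_codes())[k + 1L], ") has only ",
           n_av, " voxels available, fewer than per_class = ", per_class)
    picks[[k]] <- cand[sample.int(n_av, per_class), , drop = FALSE]
  }
  sel <- do.call(rbind, picks)
  labels <- rep(classes, each = per_class)
  ord <- sample.int(nrow(sel))
  sel <- sel[ord, , drop = FALSE]; labels <- labels[ord]

  stats_by_pair <- lapply(pairs, function(p) signature_stats(p$volume))
  patches <- matrix(0, nrow(sel), 100L)
  centers <- matrix(0L, nrow(sel), 4L,
                    dimnames = list(NULL, c("pair", "z", "y", "x")))
  d1 <- dim(avail[[1]])
  for (i in unique(sel[, "pair"])) {
    rows <- which(sel[, "pair"] == i)
    d <- dim(avail[[i]])
    lin <- sel[rows, "lin"]
    co <- arrayInd(lin, d)
    centers[rows, ] <- cbind(i, co)
    patches[rows, ] <- extract_patches_matrix(pairs[[i]]$volume, co,
                                              stats_by_pair[[i]])
  }
  structure(list(patches = patches, centers = centers,
                 labels = as.integer(labels),
                 normalization_stats = lapply(stats_by_pair, `[[`, "scale"),
                 seed = as.integer(seed)),
            class = "patch_set")
}

#' @exportS3Method base::print
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", nrow(x$patches), " patches (5 x 5 x 4)", sep = "")
  if (!is.null(x$labels))
    cat(", labels:", paste(sprintf("%d:%d", sort(unique(x$labels)),
                                   tabulate(x$labels, 4)[sort(unique(x$labels))]),
                           collapse = " "))
  cat("\n")
  invisible(x)
}

#' Split a patch set into training and validation subsets
#'
#' Stratified by class at the requested proportion, seeded.
#'
#' @param ps a `patch_set` with labels.
#' @param val_frac validation fraction (default 0.2).
#' @param seed RNG seed.
#' @return list with `train` and `val` patch sets.
#' @export
split_patch_set <- function(ps, val_frac = 0.2, seed = 1L) {
  stopifnot(inherits(ps, "patch_set"), !is.null(ps$labels))
  set.seed(as.integer(seed))
  val_idx <- unlist(lapply(sort(unique(ps$labels)), function(k) {
    idx <- which(ps$labels == k)
    sample(idx, max(1L, round(val_frac * length(idx))))
  }))
  subset_ps <- function(idx) {
    structure(list(patches = ps$patches[idx, , drop = FALSE],
                   centers = ps$centers[idx, , drop = FALSE],
                   labels = ps$labels[idx],
                   normalization_stats = ps$normalization_stats,
                   seed = ps$seed),
              class = "patch_set")
  }
  list(train = subset_ps(setdiff(seq_along(ps$labels), val_idx)),
       val = subset_ps(val_idx))
}
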