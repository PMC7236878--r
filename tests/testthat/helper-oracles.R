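# Independent oracles used against the package implementation. These stay
# deliberately naive (loops, enumeration) so they share no code path with
# what they check.

# brute-force rasterization: count voxel centres of one slice falling inside
# a disk of radius r_mm, looping over every voxel
oracle_disk_count <- function(ny, nx, dy, dx, r_mm) {
  n <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    y <- (iy - 0.5) * dy - ny * dy / 2
    x <- (ix - 0.5) * dx - nx * dx / 2
    if (sqrt(y^2 + x^2) <= r_mm) n <- n + 1L
  }
  n
}

# explicit-padding patch oracle: physically pad the slice by two replicated
# rows/columns on each side, then crop the 5x5 window
oracle_patch <- function(volume, coord, stats) {
  chs <- c("in_phase", "opposed_phase", "water", "fat")
  z <- coord[1]; y <- coord[2]; x <- coord[3]
  out <- array(0, c(5, 5, 4))
  for (ci in seq_along(chs)) {
    sl <- volume[[chs[ci]]][z, , ] / stats$scale[[chs[ci]]]
    padded <- rbind(sl[1, , drop = FALSE], sl[1, , drop = FALSE], sl,
                    sl[nrow(sl), , drop = FALSE], sl[nrow(sl), , drop = FALSE])
    padded <- cbind(padded[, 1, drop = FALSE], padded[, 1, drop = FALSE],
                    padded, padded[, ncol(padded), drop = FALSE],
                    padded[, ncol(padded), drop = FALSE])
    out[, , ci] <- padded[(y):(y + 4), (x):(x + 4)]
  }
  out
}

# all permutations of 1..n through a different algorithm than the package's:
# filter the full n^n tuple grid down to distinct tuples. A tuple of n powers
# of two sums to 2^n - 1 (popcount n) iff all entries are distinct, which
# makes the filter a vectorized one-liner.
oracle_permutations <- function(n) {
  g <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  keep <- rowSums(2^(g - 1)) == 2^n - 1
  unname(g[keep, , drop = FALSE])
}

# exact two-sided Spearman permutation p by looping over the oracle's
# permutation list with stats::cor
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- oracle_permutations(n)
  hits <- 0L
  for (i in seq_len(nrow(perms)))
    if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12) hits <- hits + 1L
  hits / nrow(perms)
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign vectors
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    ws[mask + 1] <- sum(r[signs])
  }
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# per-class voxel counting by an explicit triple loop
oracle_class_counts <- function(labels_arr, zlo, zhi) {
  counts <- integer(5)
  d <- dim(labels_arr)
  for (z in zlo:zhi) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    counts[labels_arr[z, y, x] + 1L] <- counts[labels_arr[z, y, x] + 1L] + 1L
  counts
}

# ---- shared heavyweight fixtures, built once per test run --------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small noiseless phantom shared by cheap tests
noiseless_phantom <- function() {
  fixture("noiseless", function()
    generate_phantom(phantom_params(grid_shape = c(4L, 40L, 40L),
                                    voxel_size_mm = c(5, 2.5, 2.5),
                                    muscle_radius_mm = 40,
                                    subcut_thickness_mm = 8,
                                    infiltration_fraction = 0.4,
                                    snr = Inf, seed = 91L)))
}

# the validation profile shared by the CNN and acceptance tests: a model
# trained on ten phantom realizations at SNR 20 (20,000 patches, 10 epochs)
desk_training <- function() {
  fixture("desk_training", function() {
    fracs <- seq(0.1, 0.9, length.out = 10)
    phantoms <- lapply(seq_along(fracs), function(i)
      generate_phantom(desk_phantom_params(fracs[i], seed = 1000L + i)))
    ts <- build_training_set(phantoms, per_class = 5000L, seed = 11L)
    model <- train_cnn(build_model(4L, 4L, cnn_config(epochs = 10L, seed = 5L)),
                       ts)
    list(model = model, phantoms = phantoms, patches = ts)
  })
}

# held-out phantoms at SNR 20 spanning the infiltration range, plus their
# CNN segmentations
desk_heldout <- function() {
  fixture("desk_heldout", function() {
    model <- desk_training()$model
    fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    lapply(seq_along(fracs), function(i) {
      ph <- generate_phantom(desk_phantom_params(fracs[i], seed = 7000L + i))
      list(phantom = ph, predicted = segment_volume(model, ph$volume),
           fraction = fracs[i])
    })
  })
}

# small noiseless separable training run (1,000 patches per class)
noiseless_training <- function() {
  fixture("noiseless_training", function() {
    fracs <- c(0.3, 0.6)
    phantoms <- lapply(seq_along(fracs), function(i)
      generate_phantom(phantom_params(grid_shape = c(8L, 48L, 48L),
                                      voxel_size_mm = c(5, 2.5, 2.5),
                                      infiltration_fraction = fracs[i],
                                      snr = Inf, seed = 400L + i)))
    ts <- build_training_set(phantoms, per_class = 1000L, seed = 21L)
    model <- train_cnn(build_model(4L, 4L, cnn_config(epochs = 15L,
                                                      minibatch = 256L,
                                                      seed = 3L)), ts)
    list(model = model, phantoms = phantoms, patches = ts)
  })
}
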