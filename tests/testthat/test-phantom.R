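test_that("dixon forward model follows the two-point convention", {
  expect_equal(dixon_forward(1, 0), list(in_phase = 1, opposed_phase = 1))
  expect_equal(dixon_forward(0.4, 0.4), list(in_phase = 0.8, opposed_phase = 0))
  expect_equal(dixon_forward(0.3, 0.7), list(in_phase = 1.0, opposed_phase = 0.4))
  w <- matrix(runif(12), 3); f <- matrix(runif(12), 3)
  r <- dixon_forward(w, f)
  expect_equal(r$in_phase, w + f)
  expect_equal(r$opposed_phase, abs(w - f))
  expect_error(dixon_forward(-1, 0), "nonnegative")
})

test_that("noiseless phantom satisfies the Dixon identity exactly everywhere", {
  p <- noiseless_phantom()
  v <- p$volume
  expect_identical(v$in_phase, v$water + v$fat)
  expect_identical(v$opposed_phase, abs(v$water - v$fat))
  expect_true(all(v$in_phase >= 0) && all(v$opposed_phase >= 0))
})

test_that("degenerate infiltration fractions produce pure compartments", {
  base <- function(f) phantom_params(grid_shape = c(2L, 32L, 32L),
                                     voxel_size_mm = c(5, 2.5, 2.5),
                                     muscle_radius_mm = 32,
                                     subcut_thickness_mm = 6,
                                     infiltration_fraction = f, seed = 2L)
  p0 <- generate_phantom(base(0))
  expect_identical(sum(p0$labels$labels == 3L), 0L)
  p1 <- generate_phantom(base(1))
  expect_identical(sum(p1$labels$labels == 1L), 0L)
  expect_gt(sum(p1$labels$labels == 3L), 0L)
})

test_that("bone voxel count matches brute-force disk rasterization", {
  pp <- phantom_params(grid_shape = c(3L, 36L, 36L),
                       voxel_size_mm = c(5, 2.5, 2.5),
                       bone_radius_mm = 11, bone_rim_mm = 3,
                       muscle_radius_mm = 36, subcut_thickness_mm = 7,
                       seed = 9L)
  p <- generate_phantom(pp)
  per_slice <- oracle_disk_count(36, 36, 2.5, 2.5, 11)
  expect_identical(sum(p$labels$labels == 4L), 3L * per_slice)
  # muscle compartment = muscle disk minus bone disk
  per_slice_muscle <- oracle_disk_count(36, 36, 2.5, 2.5, 36) - per_slice
  expect_identical(sum(p$labels$labels %in% c(1L, 3L)), 3L * per_slice_muscle)
})

test_that("labels conserve the voxel count and stay within the code set", {
  p <- noiseless_phantom()
  lab <- p$labels$labels
  expect_true(all(lab %in% 0:4))
  expect_identical(sum(tabulate(lab + 1L, 5L)), length(lab))
})

test_that("realized infiltration matches the target to one-voxel resolution", {
  for (f in c(0.15, 0.5, 0.85)) for (tex in c("uniform", "clustered")) {
    p <- generate_phantom(phantom_params(grid_shape = c(3L, 40L, 40L),
                                         voxel_size_mm = c(5, 2.5, 2.5),
                                         muscle_radius_mm = 40,
                                         subcut_thickness_mm = 8,
                                         infiltration_fraction = f,
                                         infiltration_texture = tex,
                                         seed = 31L))
    n_m <- p$truth$n_muscle_compartment
    expect_lte(abs(p$truth$realized_infiltration_fraction - f), 1 / n_m)
  }
})

test_that("identical parameters and seed reproduce bit-identical phantoms", {
  pp <- desk_phantom_params(0.4, seed = 123L)
  a <- generate_phantom(pp); b <- generate_phantom(pp)
  expect_identical(a$volume, b$volume)
  expect_identical(a$labels, b$labels)
})

test_that("noise scales as prescribed by the SNR", {
  pp <- desk_phantom_params(0.4, seed = 5L, snr = 10)
  p <- generate_phantom(pp)
  clean <- generate_phantom(desk_phantom_params(0.4, seed = 5L, snr = Inf))
  air <- clean$labels$labels == 0L
  resid <- p$volume$water[air]             # air has zero true water signal
  # |N(0, sigma)| has SD sigma * sqrt(1 - 2/pi)
  expect_equal(stats::sd(resid), p$truth$noise_sd * sqrt(1 - 2 / pi),
               tolerance = 0.05)
})

test_that("impossible geometry and invalid noise settings are rejected", {
  expect_error(phantom_params(bone_radius_mm = 50, muscle_radius_mm = 45),
               "smaller than")
  expect_error(phantom_params(grid_shape = c(4L, 20L, 20L),
                              voxel_size_mm = c(5, 2, 2)),
               "grid too small")
  expect_error(phantom_params(snr = 0), "snr")
  expect_error(phantom_params(snr = -3), "snr")
  expect_error(phantom_params(infiltration_fraction = 1.2), "\\[0, 1\\]")
})
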