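# hand-built label map: counts {1: 4, 2: 3, 3: 2, 4: 1} in slice 1, all
# background in slice 2
toy_labels <- function() {
  arr <- array(0L, dim = c(2L, 2L, 5L))
  arr[1, 1, ] <- c(1L, 1L, 1L, 1L, 2L)
  arr[1, 2, ] <- c(2L, 2L, 3L, 3L, 4L)
  structure(list(labels = arr, code_names = tissue_codes()),
            class = "label_map")
}

test_that("tissue fractions follow direct arithmetic on a toy map", {
  q <- tissue_fractions(toy_labels(), c(1L, 1L))
  expect_equal(unname(q$tissue_fractions), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(q$tissue_fractions), 1, tolerance = 1e-9)
  expect_equal(q$intramuscular_fat_fraction, 100 * 2 / 6)
  expect_equal(q$muscle_fraction, 100 - q$intramuscular_fat_fraction)
  expect_error(tissue_fractions(toy_labels(), c(2L, 2L)), "no in-body")
  expect_error(tissue_fractions(toy_labels(), c(3L, 4L)), "roi")
})

test_that("fractions match a brute-force counting loop on a phantom", {
  p <- noiseless_phantom()
  d <- dim(p$labels$labels)
  roi <- c(2L, 3L)
  oc <- oracle_class_counts(p$labels$labels, roi[1], roi[2])
  q <- tissue_fractions(p$labels, roi)
  expect_equal(unname(q$voxel_counts), oc, ignore_attr = TRUE)
  expect_equal(unname(q$tissue_fractions), oc[2:5] / sum(oc[2:5]))
})

test_that("intramuscular fat fraction is exactly the class-3 share of muscle", {
  counts_ff <- function(n1, n3) {
    arr <- array(0L, dim = c(1L, 1L, n1 + n3))
    arr[1, 1, ] <- c(rep(1L, n1), rep(3L, n3))
    intramuscular_fat_fraction(structure(list(labels = arr,
                                              code_names = tissue_codes()),
                                         class = "label_map"))
  }
  expect_equal(counts_ff(70, 30), 30)
  expect_equal(counts_ff(1, 0), 0)
  expect_equal(counts_ff(0, 5), 100)
})

test_that("ground-truth fat fraction recovers the generator's target", {
  p <- generate_phantom(desk_phantom_params(0.5, seed = 77L, snr = Inf))
  ff <- intramuscular_fat_fraction(p$labels, p$params$thigh_slices)
  expect_lte(abs(ff / 100 - 0.5), 1 / p$truth$n_muscle_compartment)
})

test_that("fat fraction is invariant to subcutaneous rind thickness", {
  mk <- function(subcut) generate_phantom(
    phantom_params(grid_shape = c(4L, 56L, 56L), voxel_size_mm = c(5, 2.5, 2.5),
                   muscle_radius_mm = 45, subcut_thickness_mm = subcut,
                   infiltration_fraction = 0.4, snr = Inf, seed = 33L))
  thin <- mk(10); thick <- mk(20)
  expect_identical(intramuscular_fat_fraction(thin$labels),
                   intramuscular_fat_fraction(thick$labels))
  # and invariant to any relabeling confined to classes 2 and 4
  relab <- thin$labels
  relab$labels[relab$labels == 2L] <- 4L
  expect_identical(intramuscular_fat_fraction(relab),
                   intramuscular_fat_fraction(thin$labels))
})

test_that("body-composition voxel totals honor the infiltration weight", {
  lab <- toy_labels()
  bc1 <- body_composition_voxels(lab, fat_weight = 1)
  expect_equal(bc1$total_fat_voxels, 3 + 2)
  expect_equal(bc1$total_muscle_voxels, 4)
  bc0 <- body_composition_voxels(lab, fat_weight = 0)
  expect_equal(bc0$total_fat_voxels, 3)
  # no fat classes at all
  arr <- array(1L, dim = c(1L, 2L, 2L))
  lab2 <- structure(list(labels = arr, code_names = tissue_codes()),
                    class = "label_map")
  expect_equal(body_composition_voxels(lab2)$total_fat_voxels, 0)
  expect_error(body_composition_voxels(lab, fat_weight = 2), "fat_weight")
})

test_that("voxel fat totals track the generator's analytic fat volume", {
  set.seed(10)
  subs <- seq(6, 16, length.out = 20)
  fracs <- seq(0.05, 0.95, length.out = 20)
  vox <- numeric(20); truth <- numeric(20)
  for (i in 1:20) {
    p <- generate_phantom(
      phantom_params(grid_shape = c(2L, 56L, 56L),
                     voxel_size_mm = c(5, 2.5, 2.5),
                     muscle_radius_mm = 45, subcut_thickness_mm = subs[i],
                     infiltration_fraction = fracs[i], snr = Inf,
                     seed = 500L + i))
    vox[i] <- body_composition_voxels(p$labels)$total_fat_voxels
    truth[i] <- p$truth$analytic_volumes_mm3[["fat_total"]]
  }
  expect_gte(stats::cor(vox, truth), 0.95)
})

test_that("measured fat fractions slot into the cohort's long table", {
  co <- generate_cohort(5, seed = 6L)
  co2 <- append_fat_fraction(co, "P002", "baseline", 41.5)
  expect_identical(nrow(co2), nrow(co))     # replaced, not duplicated
  expect_equal(co2$value[co2$participant_id == "P002" &
                         co2$visit == "baseline" & co2$day == 1L &
                         co2$outcome == "MRI_FF"], 41.5)
  expect_error(append_fat_fraction(co, "P001", "baseline", 150), "value")
})

test_that("dice coefficient on hand-checkable overlaps", {
  a <- array(c(1L, 1L, 2L, 2L), dim = c(1, 2, 2))
  b <- array(c(1L, 2L, 2L, 2L), dim = c(1, 2, 2))
  la <- structure(list(labels = a, code_names = tissue_codes()), class = "label_map")
  lb <- structure(list(labels = b, code_names = tissue_codes()), class = "label_map")
  expect_equal(dice_coefficient(la, lb, 1L), 2 * 1 / (2 + 1))
  expect_equal(dice_coefficient(la, lb, 2L), 2 * 2 / (2 + 3))
  expect_equal(dice_coefficient(la, la, 2L), 1)
})
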