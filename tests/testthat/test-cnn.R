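test_that("architecture matches the closed-form parameter arithmetic", {
  m <- build_model(4L, 4L, cnn_config(seed = 1L))
  np <- n_parameters(m)
  expect_identical(unname(np[["conv1"]]), 3 * 3 * 4 * 128 + 128)   # 4736
  expect_identical(unname(np[["conv2"]]), 9 * 128 * 64 + 64)
  expect_identical(unname(np[["conv3"]]), 9 * 64 * 32 + 32)
  expect_identical(unname(np[["conv4"]]), 9 * 32 * 16 + 16)
  expect_identical(unname(np[["fc"]]), 16 * 4 + 4)
  expect_identical(sum(np[grep("bn", names(np))]), 2 * (128 + 64 + 32 + 16))
  expect_error(build_model(0L, 4L), "positive")
})

test_that("spatial trajectory under floor pooling is 5 -> 2 -> 1", {
  expect_identical(dixonmuscle:::make_pool_plan(5L)$Sout, 2L)
  expect_identical(dixonmuscle:::make_pool_plan(2L)$Sout, 1L)
  # and the fc layer therefore consumes a 16-vector: forward shapes agree
  m <- build_model(4L, 4L, cnn_config(seed = 1L))
  fw <- dixonmuscle:::model_forward(m, matrix(rnorm(300), 3, 100))
  expect_identical(dim(fw$logits), c(3L, 4L))
})

test_that("softmax rows are probability vectors", {
  m <- build_model(4L, 4L, cnn_config(seed = 2L))
  fw <- dixonmuscle:::model_forward(m, matrix(rnorm(700), 7, 100))
  expect_equal(rowSums(fw$probs), rep(1, 7), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  cfg <- cnn_config(conv_filters = c(6L, 5L, 4L, 3L), seed = 7L)
  m <- build_model(4L, 4L, cfg)
  X <- matrix(rnorm(600), 6, 100)
  y <- c(1L, 2L, 3L, 4L, 1L, 2L)
  fw <- dixonmuscle:::model_forward(m, X, training = TRUE)
  Y <- matrix(0, 6, 4); Y[cbind(1:6, y)] <- 1
  gr <- dixonmuscle:::model_backward(m, fw$caches, (fw$probs - Y) / 6)
  eps <- 1e-6
  loss_of <- function(m) dixonmuscle:::cross_entropy(
    dixonmuscle:::model_forward(m, X, training = TRUE)$probs, y)
  # conv biases are cancelled by the following batch norm (gradient ~ 0),
  # so check weights, batch-norm parameters and the fc head
  for (nm in c("conv1", "conv2", "conv4", "bn1", "bn3", "fc")) {
    for (pn in setdiff(names(gr[[nm]]), "b")) {
      p0 <- m$layers[[nm]][[pn]]
      for (i in sample(length(p0), 3)) {
        m2 <- m
        m2$layers[[nm]][[pn]][i] <- p0[i] + eps
        l1 <- loss_of(m2)
        m2$layers[[nm]][[pn]][i] <- p0[i] - eps
        l0 <- loss_of(m2)
        num <- (l1 - l0) / (2 * eps)
        expect_equal(gr[[nm]][[pn]][i], num, tolerance = 1e-4,
                     label = paste0(nm, ".", pn, "[", i, "]"))
      }
    }
  }
  # fc bias has a real gradient
  i <- 2L
  m2 <- m; m2$layers$fc$b[i] <- m$layers$fc$b[i] + eps; l1 <- loss_of(m2)
  m2$layers$fc$b[i] <- m$layers$fc$b[i] - eps; l0 <- loss_of(m2)
  expect_equal(gr$fc$b[i], (l1 - l0) / (2 * eps), tolerance = 1e-4)
})

test_that("zero epochs is a no-op and training is seed-deterministic", {
  nt <- noiseless_training()
  ts <- nt$patches
  m0 <- build_model(4L, 4L, cnn_config(epochs = 0L, seed = 3L))
  m1 <- train_cnn(m0, ts)
  expect_identical(m1$layers, m0$layers)
  expect_identical(nrow(m1$history), 0L)

  cfg <- cnn_config(epochs = 2L, minibatch = 512L, seed = 19L)
  ma <- train_cnn(build_model(4L, 4L, cfg), ts)
  mb <- train_cnn(build_model(4L, 4L, cfg), ts)
  expect_identical(ma$history$val_accuracy, mb$history$val_accuracy)
  expect_identical(ma$layers$fc$W, mb$layers$fc$W)
})

test_that("missing classes and channel mismatches are rejected", {
  nt <- noiseless_training()
  ts <- nt$patches
  sub <- ts
  keep <- sub$labels != 3L
  sub$patches <- sub$patches[keep, ]; sub$labels <- sub$labels[keep]
  sub$centers <- sub$centers[keep, ]
  m <- build_model(4L, 4L, cnn_config(epochs = 1L, seed = 1L))
  expect_error(train_cnn(m, sub), "missing class")
  bad_val <- ts; bad_val$patches <- ts$patches[, 1:75]
  expect_error(train_cnn(m, ts, val_set = bad_val), "channel")
})

test_that("noiseless well-separated patches are learned to 100% accuracy", {
  nt <- noiseless_training()
  h <- nt$model$history
  expect_identical(nrow(h), 15L)
  expect_identical(h$accuracy[nrow(h)], 1)
  expect_identical(h$val_accuracy[nrow(h)], 1)
})

test_that("training loss decreases when smoothed over five epochs", {
  h <- desk_training()$model$history
  sm <- stats::filter(h$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-3))
})

test_that("segmenting a training phantom in the noiseless limit is near-perfect", {
  nt <- noiseless_training()
  ph <- nt$phantoms[[1]]
  pred <- segment_volume(nt$model, ph$volume)
  for (k in 1:3)
    expect_gte(dice_coefficient(pred, ph$labels, k), 0.99)
})

test_that("an all-air volume is labeled entirely background", {
  d <- c(2L, 20L, 20L)
  zeros <- array(0, dim = d)
  vol <- structure(list(in_phase = zeros, opposed_phase = zeros,
                        water = zeros, fat = zeros,
                        voxel_size_mm = c(5, 2, 2), thigh_slices = c(1L, 2L)),
                   class = "dixon_volume")
  pred <- segment_volume(noiseless_training()$model, vol)
  expect_true(all(pred$labels == 0L))
})

test_that("segmentation equals per-patch classification voxel by voxel", {
  nt <- noiseless_training()
  ph <- generate_phantom(desk_phantom_params(0.4, seed = 321L, snr = Inf))
  pred <- segment_volume(nt$model, ph$volume)
  st <- signature_stats(ph$volume)
  coords <- which(st$mask, arr.ind = TRUE)
  set.seed(5)
  sel <- coords[sample(nrow(coords), 500), , drop = FALSE]
  X <- dixonmuscle:::extract_patches_matrix(ph$volume, sel, st)
  cls <- classify_patches(nt$model, X)$class
  expect_identical(pred$labels[sel], cls)
})

test_that("untrained models refuse to segment", {
  m <- build_model(4L, 4L, cnn_config(seed = 1L))
  expect_error(segment_volume(m, noiseless_phantom()$volume), "untrained")
  expect_error(classify_patches(m, matrix(0, 1, 100)), "untrained")
})

test_that("predicted labels stay in the code set with background only off-mask", {
  ho <- desk_heldout()[[3]]
  pred <- ho$predicted$labels
  expect_true(all(pred %in% 0:4))
  mask <- signature_stats(ho$phantom$volume)$mask
  expect_true(all(pred[!mask] == 0L))
  expect_true(all(pred[mask] != 0L))
})
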