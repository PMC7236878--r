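#' CNN configuration
#'
#' Hyperparameters of the patch classifier. The defaults are the reproduction
#' profile: four 3x3 convolutional layers with 128, 64, 32 and 16 filters,
#' each followed by batch normalization and ReLU, 2x2 stride-2 max pooling
#' after the first two, a fully connected layer and softmax; trained for 30
#' epochs with Adam (learning rate 0.001, beta1 0.9, beta2 0.999, epsilon
#' 1e-8) at minibatch size 1024, minimizing cross-entropy. The `momentum`
#' field records the conventional 0.9 momentum setting alongside Adam; it
#' duplicates beta1 and only beta1 is operative. Any override of a default is
#' recorded in `$overridden` so run logs can surface it.
#'
#' @param conv_filters filter counts of the four convolutional layers.
#' @param kernel convolution kernel side (3).
#' @param epochs training epochs.
#' @param learning_rate,momentum,beta1,beta2,epsilon Adam settings.
#' @param minibatch minibatch size.
#' @param bn_momentum update weight of the batch-norm running statistics.
#' @param val_frac stratified validation split fraction used when no explicit
#'   validation set is supplied to [train_cnn()].
#' @param seed integer seed controlling weight initialization and minibatch
#'   shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_filters = c(128L, 64L, 32L, 16L), kernel = 3L,
                       epochs = 30L, learning_rate = 0.001, momentum = 0.9,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       minibatch = 1024L, bn_momentum = 0.1, val_frac = 0.2,
                       seed = 1L) {
  if (kernel != 3L) stop("only 3x3 kernels are supported")
  if (length(conv_filters) != 4L || any(conv_filters < 1))
    stop("conv_filters must be four positive counts")
  if (epochs < 0 || minibatch < 1) stop("invalid epochs or minibatch")
  supplied <- names(match.call())[-1]
  cfg <- structure(list(conv_filters = as.integer(conv_filters),
                        kernel = 3L, epochs = as.integer(epochs),
                        learning_rate = learning_rate, momentum = momentum,
                        beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                        minibatch = as.integer(minibatch),
                        bn_momentum = bn_momentum, val_frac = val_frac,
                        seed = as.integer(seed),
                        overridden = setdiff(supplied, "seed")),
                   class = "cnn_config")
  cfg
}

#' Build the (untrained) patch CNN
#'
#' Layer sequence on a 5 x 5 x `n_channels` input patch:
#' conv128-BN-ReLU-pool, conv64-BN-ReLU-pool, conv32-BN-ReLU, conv16-BN-ReLU,
#' fully connected, softmax. With floor-rounded 2x2/2 pooling the spatial
#' size trajectory is 5 -> 2 -> 1, so the fully connected layer maps the
#' flattened 1 x 1 x 16 feature to `n_classes` logits.
#'
#' @param n_channels signature dimensionality N (4 for the Dixon protocol).
#' @param n_classes number of tissue classes (4).
#' @param config a [cnn_config()].
#' @return An untrained `mpdl_cnn` model.
#' @export
build_model <- function(n_channels = 4L, n_classes = 4L, config = cnn_config()) {
  if (n_channels <= 0 || n_classes <= 0)
    stop("n_channels and n_classes must be positive")
  stopifnot(inherits(config, "cnn_config"))
  f <- config$conv_filters
  set.seed(config$seed)
  layers <- list(
    conv1 = conv_layer(5L, n_channels, f[1]), bn1 = bn_layer(f[1]),
    relu1 = list(type = "relu"), pool1 = list(type = "pool",
                                              plan = make_pool_plan(5L)),
    conv2 = conv_layer(2L, f[1], f[2]), bn2 = bn_layer(f[2]),
    relu2 = list(type = "relu"), pool2 = list(type = "pool",
                                              plan = make_pool_plan(2L)),
    conv3 = conv_layer(1L, f[2], f[3]), bn3 = bn_layer(f[3]),
    relu3 = list(type = "relu"),
    conv4 = conv_layer(1L, f[3], f[4]), bn4 = bn_layer(f[4]),
    relu4 = list(type = "relu"),
    fc = fc_layer(f[4], n_classes))
  structure(list(config = config, layers = layers,
                 n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 class_codes = seq_len(n_classes),
                 trained = FALSE, history = NULL, opt = list(), adam_t = 0L),
            class = "mpdl_cnn")
}

#' Count trainable parameters
#' @param model an `mpdl_cnn`.
#' @return named vector of per-layer trainable parameter counts (weights plus
#'   biases; batch-norm gain and shift included).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "mpdl_cnn"))
  vapply(model$layers, function(ly) {
    switch(ly$type,
           conv = length(ly$W) + length(ly$b),
           fc = length(ly$W) + length(ly$b),
           bn = length(ly$gamma) + length(ly$beta),
           0L)
  }, numeric(1))
}

# Full forward pass. X: B x (25 * n_channels) flat patch matrix.
# Returns logits, probs, and per-layer caches (training mode only needs
# caches; inference uses frozen batch-norm running statistics).
model_forward <- function(model, X, training = FALSE) {
  B <- nrow(X)
  # patch matrix rows are B x (25 * C); unfold to the (B*P) x C activation
  # layout (batch index fastest within each spatial position)
  act <- X
  dim(act) <- c(B * 25L, model$n_channels)
  caches <- vector("list", length(model$layers))
  layers <- model$layers
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = conv_forward(ly, act, B),
      bn = bn_forward(ly, act, training),
      relu = relu_forward(act),
      pool = pool_forward(ly, act, B),
      fc = fc_forward(ly, act))
    if (ly$type == "bn" && training) {
      mom <- ly$momentum
      layers[[i]]$run_mean <- (1 - mom) * ly$run_mean + mom * r$cache$batch_mean
      layers[[i]]$run_var <- (1 - mom) * ly$run_var + mom * r$cache$batch_var
    }
    act <- r$out
    caches[[i]] <- r$cache
    # conv/bn/relu keep the (B*P) x C layout; after pool2 P = 1 so the fc
    # layer sees a plain B x 16 matrix
  }
  list(logits = act, probs = softmax_rows(act), caches = caches,
       layers = layers)
}

model_backward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  d <- dOut
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    r <- switch(ly$type,
      conv = conv_backward(ly, d, caches[[i]]),
      bn = bn_backward(ly, d, caches[[i]]),
      relu = list(dX = d * caches[[i]]$mask, grads = NULL),
      pool = pool_backward(ly, d, caches[[i]]),
      fc = fc_backward(ly, d, caches[[i]]))
    grads[[i]] <- r$grads
    d <- r$dX
  }
  grads
}

apply_adam <- function(model, grads) {
  cfg <- model$config
  model$adam_t <- model$adam_t + 1L
  t <- model$adam_t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    for (pn in names(g)) {
      key <- paste0(nm, ".", pn)
      upd <- adam_step(model$layers[[nm]][[pn]], g[[pn]], model$opt[[key]],
                       t, cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$epsilon)
      model$layers[[nm]][[pn]] <- upd$param
      model$opt[[key]] <- upd$state
    }
  }
  model
}

label_to_index <- function(model, labels) {
  idx <- match(labels, model$class_codes)
  if (anyNA(idx)) stop("labels outside the model's class codes")
  idx
}

#' Train the patch CNN
#'
#' Minibatch Adam on cross-entropy for `config$epochs` epochs. If no
#' validation set is given, a stratified `val_frac` split of the training set
#' is held out. Deterministic given the config seed. With `epochs = 0` the
#' model is returned unchanged with an empty history.
#'
#' @param model an `mpdl_cnn` from [build_model()].
#' @param train_set a labeled `patch_set`; all classes 1-4 must be present.
#' @param val_set optional labeled `patch_set` for validation metrics.
#' @param config optional [cnn_config()] override (defaults to the model's).
#' @return The trained model; `$history` has one row per epoch (loss and
#'   accuracy on training minibatches, validation loss and accuracy).
#' @export
train_cnn <- function(model, train_set, val_set = NULL, config = model$config) {
  stopifnot(inherits(model, "mpdl_cnn"), inherits(train_set, "patch_set"))
  model$config <- config
  if (is.null(train_set$labels)) stop("train_set must be labeled")
  present <- sort(unique(train_set$labels))
  missing <- setdiff(model$class_codes, present)
  if (length(missing))
    stop("training set is missing class(es) ", paste(missing, collapse = ", "))
  if (ncol(train_set$patches) != 25L * model$n_channels)
    stop("training patches do not match the model's channel count")
  if (config$epochs == 0L) {
    model$history <- data.frame()
    return(model)
  }
  if (is.null(val_set)) {
    sp <- split_patch_set(train_set, config$val_frac, seed = config$seed)
    train_set <- sp$train; val_set <- sp$val
  }
  if (ncol(val_set$patches) != ncol(train_set$patches))
    stop("validation patches do not match the training channel count")

  X <- train_set$patches
  y <- label_to_index(model, train_set$labels)
  n <- nrow(X)
  set.seed(config$seed)
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$minibatch)
    ep_loss <- 0; ep_hits <- 0L
    for (s in starts) {
      bi <- ord[s:min(s + config$minibatch - 1L, n)]
      Xb <- X[bi, , drop = FALSE]
      yb <- y[bi]
      fw <- model_forward(model, Xb, training = TRUE)
      model$layers <- fw$layers                     # updated BN running stats
      loss <- cross_entropy(fw$probs, yb)
      pred <- max.col(fw$probs, "first")
      ep_loss <- ep_loss + loss * length(bi)
      ep_hits <- ep_hits + sum(pred == yb)
      Yb <- matrix(0, length(bi), model$n_classes)
      Yb[cbind(seq_along(yb), yb)] <- 1
      dlogits <- (fw$probs - Yb) / length(bi)
      grads <- model_backward(model, fw$caches, dlogits)
      model <- apply_adam(model, grads)
    }
    val <- evaluate_cnn(model, val_set)
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                             accuracy = ep_hits / n,
                             val_loss = val$loss, val_accuracy = val$accuracy)
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Evaluate a model on a labeled patch set
#' @param model an `mpdl_cnn`.
#' @param ps a labeled `patch_set`.
#' @return list with `loss` and `accuracy`.
#' @export
evaluate_cnn <- function(model, ps) {
  fw <- model_forward(model, ps$patches, training = FALSE)
  y <- label_to_index(model, ps$labels)
  list(loss = cross_entropy(fw$probs, y),
       accuracy = mean(max.col(fw$probs, "first") == y))
}

#' Classify signature patches
#'
#' @param model a trained `mpdl_cnn`.
#' @param patches n x 100 flat patch matrix (or a `patch_set`).
#' @return list with `class` (tissue codes) and `probs` (n x 4 softmax rows).
#' @export
classify_patches <- function(model, patches) {
  if (inherits(patches, "patch_set")) patches <- patches$patches
  if (!model$trained) stop("model is untrained")
  fw <- model_forward(model, patches, training = FALSE)
  list(class = model$class_codes[max.col(fw$probs, "first")],
       probs = fw$probs)
}

#' Segment a Dixon volume
#'
#' Background (air) voxels are assigned label 0 by the body mask without CNN
#' evaluation; every in-body voxel receives the argmax softmax class of its
#' 5 x 5 x N signature patch, ties broken toward the lowest class code.
#' Batch-norm inference uses frozen running statistics.
#'
#' @param model a trained `mpdl_cnn`.
#' @param volume a `dixon_volume` with the training channel order.
#' @param batch_size voxels classified per forward pass.
#' @return A `label_map` aligned voxel-for-voxel with the input.
#' @export
segment_volume <- function(model, volume, batch_size = 8192L) {
  stopifnot(inherits(model, "mpdl_cnn"), inherits(volume, "dixon_volume"))
  if (!model$trained) stop("model is untrained")
  st <- signature_stats(volume)
  labels <- array(0L, dim = dim(volume$in_phase))
  coords <- which(st$mask, arr.ind = TRUE)
  if (nrow(coords)) {
    for (s in seq(1L, nrow(coords), by = batch_size)) {
      chunk <- coords[s:min(s + batch_size - 1L, nrow(coords)), , drop = FALSE]
      Xb <- extract_patches_matrix(volume, chunk, st)
      fw <- model_forward(model, Xb, training = FALSE)
      labels[chunk] <- model$class_codes[max.col(fw$probs, "first")]
    }
  }
  structure(list(labels = labels, code_names = tissue_codes()),
            class = "label_map")
}

#' @exportS3Method base::print
print.mpdl_cnn <- function(x, ...) {
  f <- x$config$conv_filters
  cat("<mpdl_cnn> conv", paste(f, collapse = "-"),
      "+ BN/ReLU, pool after conv1-2, FC ->", x$n_classes, "classes;",
      if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
      else "untrained", "\n")
  cat("  trainable parameters:", sum(n_parameters(x)), "\n")
  invisible(x)
}
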