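# Layer primitives of the patch CNN.
#
# Activations are kept as dense matrices of shape (B * P) x C, where B is the
# minibatch size, P the number of spatial positions of the current feature
# map (row order: batch index fastest, then position, position order x
# fastest then y), and C the channel count. Convolutions are evaluated as
# im2col matrix products so all heavy arithmetic runs through BLAS; the
# backward scatter of im2col is a precomputed sparse indicator product.

# im2col plan for a 3x3 same-padded convolution on an S x S feature map with
# Cin channels. Column order of the patch matrix (and row order of the weight
# matrix): kernel x-offset fastest, then y-offset, then input channel.
make_conv_plan <- function(S, Cin) {
  P <- S * S
  ncol_in <- P * Cin
  nine <- 9L * Cin
  # index map ordered position-fastest, kernel column j slowest, so the
  # gathered B x (P*nine) matrix refolds to (B*P) x nine by a plain dim
  # change (batch fastest within each position) with no transposition
  idx <- integer(P * nine)
  for (p in seq_len(P)) {
    py <- (p - 1L) %/% S + 1L; px <- (p - 1L) %% S + 1L
    for (c in seq_len(Cin)) for (ky in -1:1) for (kx in -1:1) {
      j <- (kx + 2L) + 3L * (ky + 1L) + 9L * (c - 1L)
      sx <- px + kx; sy <- py + ky
      idx[(j - 1L) * P + p] <-
        if (sx < 1 || sx > S || sy < 1 || sy > S) ncol_in + 1L
        else sx + S * (sy - 1L) + P * (c - 1L)
    }
  }
  scatter <- Matrix::sparseMatrix(i = seq_along(idx), j = idx,
                                  x = 1, dims = c(length(idx), ncol_in + 1L))
  list(S = S, Cin = Cin, P = P, nine = nine, ncol_in = ncol_in,
       idx = idx, scatter = scatter)
}

conv_layer <- function(S, Cin, Cout) {
  fan_in <- 9L * Cin
  list(type = "conv", plan = make_conv_plan(S, Cin), Cout = Cout,
       W = matrix(stats::rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)),
                  fan_in, Cout),
       b = numeric(Cout))
}

conv_forward <- function(layer, X, B) {
  pl <- layer$plan
  # incoming activations are (B*P) x Cin (batch fastest); fold to the
  # B x (P*Cin) image layout the im2col index map addresses
  dim(X) <- c(B, pl$P * pl$Cin)
  Xaug <- cbind(X, 0)
  Dm <- Xaug[, pl$idx, drop = FALSE]                   # B x (P * nine)
  dim(Dm) <- c(B * pl$P, pl$nine)
  out <- Dm %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, cache = list(Dm = Dm, B = B))
}

conv_backward <- function(layer, dOut, cache) {
  pl <- layer$plan; B <- cache$B
  dW <- crossprod(cache$Dm, dOut)
  db <- colSums(dOut)
  dDm <- dOut %*% t(layer$W)                           # (B*P) x nine
  dim(dDm) <- c(B, pl$P * pl$nine)
  dXaug <- as.matrix(dDm %*% pl$scatter)
  dX <- dXaug[, seq_len(pl$ncol_in), drop = FALSE]
  dim(dX) <- c(B * pl$P, pl$Cin)                       # back to (B*P) x Cin
  list(dX = dX, grads = list(W = dW, b = db))
}

# 2x2 stride-2 max pooling with floor rounding on odd sizes (trailing
# row/column dropped).
make_pool_plan <- function(Sin) {
  Sout <- Sin %/% 2L
  Pout <- Sout * Sout
  pos <- matrix(0L, Pout, 4L)
  q <- 0L
  for (qy in seq_len(Sout)) for (qx in seq_len(Sout)) {
    q <- q + 1L
    m <- 0L
    for (my in 0:1) for (mx in 0:1) {
      m <- m + 1L
      px <- 2L * (qx - 1L) + mx + 1L
      py <- 2L * (qy - 1L) + my + 1L
      pos[q, m] <- px + Sin * (py - 1L)
    }
  }
  list(Sin = Sin, Sout = Sout, Pin = Sin * Sin, Pout = Pout, pos = pos)
}

pool_forward <- function(layer, X, B) {
  pl <- layer$plan
  rowsel <- lapply(1:4, function(m)
    as.vector(outer(seq_len(B), (pl$pos[, m] - 1L) * B, "+")))
  cand <- lapply(rowsel, function(rs) X[rs, , drop = FALSE])
  amax <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  taken <- matrix(FALSE, nrow(amax), ncol(amax))
  masks <- vector("list", 4)
  for (m in 1:4) {
    masks[[m]] <- (cand[[m]] == amax) & !taken
    taken <- taken | masks[[m]]
  }
  list(out = amax,
       cache = list(rowsel = rowsel, masks = masks, B = B,
                    nrow_in = nrow(X), ncol_in = ncol(X)))
}

pool_backward <- function(layer, dOut, cache) {
  dX <- matrix(0, cache$nrow_in, cache$ncol_in)
  for (m in 1:4) {
    rs <- cache$rowsel[[m]]
    dX[rs, ] <- dX[rs, ] + dOut * cache$masks[[m]]
  }
  list(dX = dX, grads = NULL)
}

bn_layer <- function(C) {
  list(type = "bn", C = C, gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C), eps = 1e-5, momentum = 0.1)
}

# column-broadcast helpers (much cheaper than sweep on large activations)
col_mul <- function(X, v) X * rep(v, each = nrow(X))
col_add <- function(X, v) X + rep(v, each = nrow(X))

bn_forward <- function(layer, X, training) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- col_add(X, -mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + layer$eps)
    xhat <- col_mul(xc, inv)
    out <- col_add(col_mul(xhat, layer$gamma), layer$beta)
    list(out = out,
         cache = list(xhat = xhat, inv = inv, batch_mean = mu, batch_var = v))
  } else {
    inv <- 1 / sqrt(layer$run_var + layer$eps)
    xhat <- col_mul(col_add(X, -layer$run_mean), inv)
    out <- col_add(col_mul(xhat, layer$gamma), layer$beta)
    list(out = out, cache = NULL)
  }
}

bn_backward <- function(layer, dOut, cache) {
  N <- nrow(dOut)
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- col_mul(dOut, layer$gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- col_add(N * dxhat, -s1) - col_mul(xhat, s2)
  dX <- col_mul(dX, cache$inv / N)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(X) {
  out <- X
  out[out < 0] <- 0
  list(out = out, cache = list(mask = X > 0))
}

fc_layer <- function(Cin, Cout) {
  list(type = "fc", Cin = Cin, Cout = Cout,
       W = matrix(stats::rnorm(Cin * Cout, sd = sqrt(2 / Cin)), Cin, Cout),
       b = numeric(Cout))
}

fc_forward <- function(layer, X) {
  out <- X %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, cache = list(X = X))
}

fc_backward <- function(layer, dOut, cache) {
  list(dX = dOut %*% t(layer$W),
       grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)))
}

softmax_rows <- function(logits) {
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, "first"))]
  e <- exp(logits - mx)
  e / rowSums(e)
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

# Adam parameter update. state: list(m =, v =); returns updated param + state.
adam_step <- function(param, grad, state, t, lr, beta1, beta2, eps) {
  if (is.null(state)) state <- list(m = param * 0, v = param * 0)
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
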