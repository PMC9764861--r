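# Neural-network primitives: 2-D convolution via im2col + GEMM, batch
# normalization, SiLU, and Adam. Everything operates on batches stored as
# matrices [n_features x batch] so the heavy lifting is BLAS matrix products.
# All layer code is internal; the user-facing surface is in model.R/train.R.

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# Valid-padding output size along one axis.
conv_out_len <- function(n, k, s) {
  if (n < k) return(0L)
  as.integer((n - k) %/% s + 1L)
}

# Geometry of one conv layer on input (C_in, H, W) with kernel (kh, kw) and
# stride (sh, sw). The im2col index matrix [K x P] maps (kernel offset,
# output position) to a linear index into one sample's input array; it is
# built lazily and cached because full-scale layers need tens of MB.
conv_geom <- function(C_in, H, W, kh, kw, sh, sw, F_out) {
  H_out <- conv_out_len(H, kh, sh)
  W_out <- conv_out_len(W, kw, sw)
  list(C_in = C_in, H = H, W = W, kh = kh, kw = kw, sh = sh, sw = sw,
       F_out = F_out, H_out = H_out, W_out = W_out,
       K = C_in * kh * kw, P = H_out * W_out,
       n_in = C_in * H * W, n_out = F_out * H_out * W_out,
       idx_cache = new.env(parent = emptyenv()))
}

conv_idx <- function(g) {
  if (is.null(g$idx_cache$idx)) {
    gk <- expand.grid(c = seq_len(g$C_in), dh = seq_len(g$kh),
                      dw = seq_len(g$kw))
    gp <- expand.grid(ho = seq_len(g$H_out), wo = seq_len(g$W_out))
    a <- gk$c + g$C_in * (gk$dh - 1L) + g$C_in * g$H * (gk$dw - 1L)
    b <- g$C_in * g$sh * (gp$ho - 1L) + g$C_in * g$H * g$sw * (gp$wo - 1L)
    g$idx_cache$idx <- outer(as.integer(a), as.integer(b), `+`)
  }
  g$idx_cache$idx
}

# Expanded batch index [K x P*B], cached per batch size (the expansion is a
# quarter of the step cost if redone every batch).
conv_big_idx <- function(g, B) {
  cache <- g$idx_cache
  if (is.null(cache$big) || !identical(cache$B, B)) {
    big <- outer(as.vector(conv_idx(g)), (seq_len(B) - 1L) * g$n_in, `+`)
    dim(big) <- c(g$K, g$P * B)
    cache$big <- big
    cache$B <- B
  }
  cache$big
}

# im2col for a batch: X is [n_in x B]; returns [K x P*B] plus the expanded
# index (reused by the backward scatter).
im2col <- function(X, g) {
  big <- conv_big_idx(g, ncol(X))
  cols <- X[big]
  dim(cols) <- c(g$K, g$P * ncol(X))
  list(cols = cols, big = big)
}

conv_forward <- function(X, W, b, g) {
  ic <- im2col(X, g)
  Y <- W %*% ic$cols + b
  list(Y = Y, cols = ic$cols, big = ic$big)
}

# dY: [F x P*B]; returns gradients and (optionally) dX [n_in x B]
conv_backward <- function(dY, X, W, cache, g, need_dx = TRUE) {
  dW <- tcrossprod(dY, cache$cols)
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    dcols <- crossprod(W, dY) # [K x P*B]
    B <- ncol(X)
    dX <- numeric(g$n_in * B)
    for (k in seq_len(g$K)) {
      ii <- cache$big[k, ]
      dX[ii] <- dX[ii] + dcols[k, ]
    }
    dim(dX) <- c(g$n_in, B)
  }
  list(dW = dW, db = db, dX = dX)
}

BN_EPS <- 1e-5

bn_forward <- function(Z, gamma, beta, state, training) {
  if (training) {
    mu <- rowMeans(Z)
    v <- rowMeans(Z^2) - mu^2
    v <- pmax(v, 0)
    m <- ncol(Z)
    unbiased <- if (m > 1) v * m / (m - 1) else v
    state$running_mean <- 0.9 * state$running_mean + 0.1 * mu
    state$running_var <- 0.9 * state$running_var + 0.1 * unbiased
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (Z - mu) * inv_sd
  list(Y = gamma * xhat + beta, xhat = xhat, inv_sd = inv_sd, state = state)
}

bn_backward <- function(dY, cache, gamma, training) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  if (training) {
    dZ <- cache$inv_sd *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dZ <- dxhat * cache$inv_sd
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Drop the cached batch-expanded conv indices (tens of MB for wide layers);
# they are rebuilt lazily on the next forward pass.
clear_conv_caches <- function(model) {
  for (g in model$geoms) {
    g$idx_cache$big <- NULL
    g$idx_cache$B <- NULL
  }
  invisible(model)
}

# Adam optimizer state over a flat list of parameter arrays.
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr <- sqrt(1 - beta2^opt$t) / (1 - beta1^opt$t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * corr * opt$m[[nm]] / (sqrt(opt$v[[nm]]) + eps)
  }
  list(params = params, opt = opt)
}
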