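#' Configuration of the stacked-tensor convolutional age regressor
#'
#' The model takes a segment of raw EEG `[n_channels x seg_samples]`,
#' expands it into a stacked tensor of `stack_depth` cyclically
#' channel-rolled copies (see [stacked_transform()]), and applies four
#' blocks of (valid-padding 2-D convolution, batch normalization, SiLU),
#' followed by global average pooling and a linear layer producing one
#' scalar: the predicted age in years. Kernels are `(electrode, time)`
#' pairs; the common stride `(1, 3)` preserves the electrode axis while
#' downsampling time.
#'
#' The default configuration is the full-scale architecture for 26-channel,
#' 5-s, 500-Hz segments: kernels (7,64), (7,32), (7,16), (7,8), widths 16,
#' 32, 64, 128, which yields a pre-pool feature map of shape (128, 2, 25).
#' Construction fails with an explicit message if any feature-map dimension
#' collapses below 1, so infeasible kernel/stride/segment combinations are
#' caught before any training.
#'
#' @param n_channels number of EEG channels (electrode axis of the input).
#' @param seg_samples segment length in samples (time axis of the input).
#' @param stack_depth number of rolled copies in the stacked tensor.
#' @param conv_kernels list of 4 `(height, width)` kernel sizes.
#' @param conv_stride `(height, width)` stride shared by all blocks.
#' @param conv_widths output channel counts of the 4 blocks.
#' @param activation `"silu"` (the sigmoid linear unit, the default) or
#'   `"identity"` (no nonlinearity; with evaluation-mode batch norm the whole
#'   network is then affine in its input, which is useful for attribution
#'   axioms and debugging).
#' @return An object of class `model_config`, with the derived per-block
#'   feature-map shapes in `$shapes`.
#' @export
model_config <- function(n_channels = 26, seg_samples = 2500, stack_depth = 4,
                         conv_kernels = list(c(7, 64), c(7, 32),
                                             c(7, 16), c(7, 8)),
                         conv_stride = c(1, 3),
                         conv_widths = c(16, 32, 64, 128),
                         activation = c("silu", "identity")) {
  activation <- match.arg(activation)
  check_count(n_channels, "n_channels")
  check_count(seg_samples, "seg_samples")
  check_count(stack_depth, "stack_depth")
  if (length(conv_kernels) != length(conv_widths)) {
    stopf("conv_kernels and conv_widths must have equal length")
  }
  shapes <- list()
  C_in <- stack_depth; H <- n_channels; W <- seg_samples
  for (l in seq_along(conv_kernels)) {
    k <- conv_kernels[[l]]
    H2 <- conv_out_len(H, k[1], conv_stride[1])
    W2 <- conv_out_len(W, k[2], conv_stride[2])
    if (H2 < 1L || W2 < 1L) {
      stopf(paste0(
        "block %d collapses the feature map: input (%d x %d), kernel ",
        "(%d x %d), stride (%d x %d) -> (%d x %d); reduce kernels or ",
        "strides, or enlarge the segment"),
        l, H, W, k[1], k[2], conv_stride[1], conv_stride[2], H2, W2)
    }
    shapes[[l]] <- c(conv_widths[l], H2, W2)
    C_in <- conv_widths[l]; H <- H2; W <- W2
  }
  structure(
    list(n_channels = as.integer(n_channels),
         seg_samples = as.integer(seg_samples),
         stack_depth = as.integer(stack_depth),
         conv_kernels = lapply(conv_kernels, as.integer),
         conv_stride = as.integer(conv_stride),
         conv_widths = as.integer(conv_widths),
         activation = activation,
         shapes = shapes),
    class = "model_config"
  )
}

#' Architecture presets
#'
#' `"full"` is the full-scale architecture (26 channels, 5-s 500-Hz
#' segments). `"tiny"` is a desk-scale variant for 8-channel, 2-s, 250-Hz
#' data (kernels (3,16), (3,8), (2,8), (2,4), widths 8/16/32/64) that trains
#' in minutes on one CPU and is used throughout the test suite.
#'
#' @param preset `"full"` or `"tiny"`.
#' @return A [model_config()].
#' @export
model_preset <- function(preset = c("full", "tiny")) {
  preset <- match.arg(preset)
  switch(preset,
    full = model_config(),
    tiny = model_config(
      n_channels = 8, seg_samples = 500, stack_depth = 4,
      conv_kernels = list(c(3, 16), c(3, 8), c(2, 8), c(2, 4)),
      conv_stride = c(1, 3),
      conv_widths = c(8, 16, 32, 64)
    )
  )
}

# permutation mapping a segment vector (C x L, column-major) onto the
# stacked tensor vector (depth x C x L): slice j holds the input with
# channel rows cyclically rolled by j * floor(C/depth)
stack_perm <- function(C, L, depth) {
  roll <- C %/% depth
  g <- expand.grid(j = 0:(depth - 1L), i = seq_len(C), t = seq_len(L))
  as.integer(((g$i - 1L + g$j * roll) %% C) + 1L + (g$t - 1L) * C)
}

#' Stacked-tensor transform
#'
#' Expands a segment `[C x L]` into a `[depth x C x L]` tensor whose slice
#' `j` (0-based) is the segment with its channel rows cyclically rolled by
#' `j * floor(C/depth)` positions (slice 0 is the identity copy). Stacking
#' rolled copies puts every electrode into several vertical neighborhoods,
#' enlarging the electrode receptive field of the first convolutional layer.
#'
#' @param segment_data numeric matrix `[C x L]`.
#' @param depth number of rolled copies (>= 1).
#' @return A numeric array `[depth x C x L]`.
#' @export
stacked_transform <- function(segment_data, depth = 4) {
  stopifnot(is.matrix(segment_data))
  check_count(depth, "depth")
  C <- nrow(segment_data); L <- ncol(segment_data)
  perm <- stack_perm(C, L, depth)
  array(as.vector(segment_data)[perm], dim = c(depth, C, L))
}

#' Construct an (untrained) convolutional age regressor
#'
#' Initializes all convolution and linear weights with the fan-in uniform
#' scheme `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` under the given seed; batch
#' normalization scales start at 1, shifts at 0, running statistics at
#' (0, 1). Use [train_age_model()] to fit it.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `age_model`.
#' @export
age_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  n_blocks <- length(config$conv_kernels)
  geoms <- vector("list", n_blocks)
  C_in <- config$stack_depth; H <- config$n_channels; W <- config$seg_samples
  for (l in seq_len(n_blocks)) {
    k <- config$conv_kernels[[l]]
    geoms[[l]] <- conv_geom(C_in, H, W, k[1], k[2],
                            config$conv_stride[1], config$conv_stride[2],
                            config$conv_widths[l])
    C_in <- config$conv_widths[l]
    H <- geoms[[l]]$H_out; W <- geoms[[l]]$W_out
  }
  params <- list()
  bn <- vector("list", n_blocks)
  with_seed(seed, {
    for (l in seq_len(n_blocks)) {
      g <- geoms[[l]]
      bound <- 1 / sqrt(g$K)
      params[[paste0("W", l)]] <-
        matrix(stats::runif(g$F_out * g$K, -bound, bound), g$F_out, g$K)
      params[[paste0("b", l)]] <- stats::runif(g$F_out, -bound, bound)
      params[[paste0("gamma", l)]] <- rep(1, g$F_out)
      params[[paste0("beta", l)]] <- rep(0, g$F_out)
      bn[[l]] <- list(running_mean = rep(0, g$F_out),
                      running_var = rep(1, g$F_out))
    }
    F_last <- config$conv_widths[n_blocks]
    bound <- 1 / sqrt(F_last)
    params$w_head <- stats::runif(F_last, -bound, bound)
    params$b_head <- stats::runif(1, -bound, bound)
  })
  structure(
    list(config = config, geoms = geoms, params = params, bn = bn,
         perm = stack_perm(config$n_channels, config$seg_samples,
                           config$stack_depth),
         n_in = config$stack_depth * config$n_channels * config$seg_samples,
         trained = FALSE, history = NULL, seed = as.integer(seed)),
    class = "age_model"
  )
}

# Build the stacked input matrix [n_in x B] from an eeg_segments object (or
# a [C x L x B] array) for the given segment indices.
model_input <- function(model, segments, idx = NULL) {
  data <- if (inherits(segments, "eeg_segments")) segments$data else segments
  stopifnot(is.array(data))
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  cfg <- model$config
  if (dim(data)[1] != cfg$n_channels || dim(data)[2] != cfg$seg_samples) {
    stopf("input segments are %d x %d but the model expects %d x %d",
          dim(data)[1], dim(data)[2], cfg$n_channels, cfg$seg_samples)
  }
  if (is.null(idx)) idx <- seq_len(dim(data)[3])
  X <- data
  dim(X) <- c(dim(data)[1] * dim(data)[2], dim(data)[3])
  X[model$perm, idx, drop = FALSE]
}

# Forward pass over a stacked batch X [n_in x B]. Returns predictions and,
# when keep_cache, everything the backward pass needs. In training mode the
# returned `bn` carries updated running statistics.
forward_pass <- function(model, X, training = FALSE, keep_cache = FALSE) {
  n_blocks <- length(model$geoms)
  B <- ncol(X)
  caches <- if (keep_cache) vector("list", n_blocks) else NULL
  bn <- model$bn
  cur <- X
  for (l in seq_len(n_blocks)) {
    g <- model$geoms[[l]]
    cf <- conv_forward(cur, model$params[[paste0("W", l)]],
                       model$params[[paste0("b", l)]], g)
    bf <- bn_forward(cf$Y, model$params[[paste0("gamma", l)]],
                     model$params[[paste0("beta", l)]], bn[[l]], training)
    bn[[l]] <- bf$state
    act <- if (model$config$activation == "silu") silu(bf$Y) else bf$Y
    if (keep_cache) {
      caches[[l]] <- list(X = cur, cols = cf$cols, big = cf$big,
                          bn = bf[c("xhat", "inv_sd")], pre_act = bf$Y)
    }
    cur <- act
    dim(cur) <- c(g$F_out * g$P, B)
  }
  g_last <- model$geoms[[n_blocks]]
  feat <- cur
  dim(feat) <- c(g_last$F_out, g_last$P, B)
  gap <- colMeans(aperm(feat, c(2, 1, 3))) # [F x B]
  dim(gap) <- c(g_last$F_out, B)
  yhat <- as.vector(model$params$w_head %*% gap + model$params$b_head)
  list(yhat = yhat, gap = gap, caches = caches, bn = bn)
}

# Backward pass from d(loss)/d(yhat). Returns parameter gradients and, if
# requested, the gradient with respect to the stacked input.
backward_pass <- function(model, fwd, dyhat, training = TRUE,
                          need_input_grad = FALSE) {
  n_blocks <- length(model$geoms)
  B <- length(dyhat)
  grads <- list()
  grads$w_head <- as.vector(fwd$gap %*% dyhat)
  grads$b_head <- sum(dyhat)
  g_last <- model$geoms[[n_blocks]]
  dgap <- outer(model$params$w_head, dyhat) # [F x B]
  # spread the GAP gradient uniformly over spatial positions
  dcur <- array(0, dim = c(g_last$F_out, g_last$P, B))
  for (p in seq_len(g_last$P)) dcur[, p, ] <- dgap / g_last$P
  dim(dcur) <- c(g_last$F_out, g_last$P * B)
  for (l in rev(seq_len(n_blocks))) {
    g <- model$geoms[[l]]
    cache <- fwd$caches[[l]]
    dact <- if (model$config$activation == "silu") {
      dcur * silu_grad(cache$pre_act)
    } else dcur
    bb <- bn_backward(dact, cache$bn, model$params[[paste0("gamma", l)]],
                      training)
    grads[[paste0("gamma", l)]] <- bb$dgamma
    grads[[paste0("beta", l)]] <- bb$dbeta
    need_dx <- l > 1L || need_input_grad
    cb <- conv_backward(bb$dZ, cache$X, model$params[[paste0("W", l)]],
                        cache, g, need_dx = need_dx)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    if (l > 1L) {
      # the input of block l is the activation of block l-1, same layout
      dcur <- cb$dX
      dim(dcur) <- c(model$geoms[[l - 1L]]$F_out,
                     model$geoms[[l - 1L]]$P * ncol(cb$dX))
    } else if (need_input_grad) {
      grads$input <- cb$dX
    }
  }
  grads
}

#' Predict per-segment ages
#'
#' Runs the model in evaluation mode (batch normalization uses running
#' statistics, no augmentation) over segments and returns one predicted age
#' per segment, clamped to be non-negative.
#'
#' @param object an [age_model()].
#' @param newdata an `eeg_segments` object or a `[C x L x N]` array.
#' @param batch_size forward-pass batch size.
#' @param clamp clamp predictions at 0 (the default; raw network output can
#'   be slightly negative).
#' @param ... unused.
#' @return Numeric vector of predicted ages (years), one per segment.
#' @export
predict.age_model <- function(object, newdata, batch_size = 64L,
                              clamp = TRUE, ...) {
  X <- model_input(object, newdata)
  N <- ncol(X)
  out <- numeric(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    out[idx] <- forward_pass(object, X[, idx, drop = FALSE])$yhat
  }
  if (any(!is.finite(out))) stopf("model produced non-finite predictions")
  if (clamp) out <- pmax(out, 0)
  out
}

#' Number of trainable parameters
#' @param model an [age_model()].
#' @return Integer: total count over convolution weights/biases, batch-norm
#'   scales/shifts, and the linear head.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "age_model"))
  sum(vapply(model$params, length, 0L))
}

#' @export
coef.age_model <- function(object, ...) {
  unlist(object$params)
}

#' @export
print.age_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<age_model> %s, stacked input (%d x %d x %d), %d parameters\n",
    if (x$trained) "trained" else "untrained",
    cfg$stack_depth, cfg$n_channels, cfg$seg_samples, count_parameters(x)))
  for (l in seq_along(cfg$shapes)) {
    k <- cfg$conv_kernels[[l]]
    cat(sprintf("  block %d: conv %dx%d stride (%d,%d) -> (%s), BN, SiLU\n",
                l, k[1], k[2], cfg$conv_stride[1], cfg$conv_stride[2],
                paste(cfg$shapes[[l]], collapse = ", ")))
  }
  cat("  global average pool -> linear -> age (years)\n")
  if (!is.null(x$history)) {
    best <- min(x$history$val_mae)
    cat(sprintf("  %d epochs trained, best validation MAE %.2f years\n",
                nrow(x$history), best))
  }
  invisible(x)
}

#' @export
summary.age_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history of a fitted age model
#' @param x a trained [age_model()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.age_model <- function(x, ...) {
  if (is.null(x$history) || nrow(x$history) == 0) {
    stopf("model has no training history")
  }
  h <- x$history
  graphics::plot(h$epoch, h$val_mae, type = "b", xlab = "epoch",
                 ylab = "MAE (years)", ylim = range(c(h$val_mae, h$train_loss)),
                 ...)
  graphics::lines(h$epoch, h$train_loss, type = "b", lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("validation MAE", "training loss"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
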