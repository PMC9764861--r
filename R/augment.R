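#' Stochastic augmentation configuration
#'
#' The five segment-level transforms applied (each with its own Bernoulli
#' draw, in this order) to a training segment before it enters the model:
#'
#' 1. additive i.i.d. Gaussian noise, one standard deviation per call drawn
#'    uniformly from `noise_std_range` uV (probability `p_noise`);
#' 2. dropout: in each of `k` channels (`k` uniform on
#'    `dropout_channels_range`, channels chosen without replacement), a run of
#'    `B_k` consecutive time points (`B_k` uniform on `dropout_len_range`,
#'    drawn per channel, start uniform) is zeroed (probability `p_dropout`);
#' 3. per-channel amplitude scaling by a multiplier uniform on `amp_range`
#'    (probability `p_amp`);
#' 4. time warp: the time axis is linearly resampled by a factor uniform on
#'    `warp_range`, then center-cropped (stretch) or edge-padded (shrink)
#'    back to the original length (probability `p_warp`);
#' 5. time reversal of all channels (probability `p_reverse`).
#'
#' Defaults are the tuned values for 5-s, 500-Hz segments: dropout runs of up
#' to 1800 samples (3.6 s) in up to 8 of 26 channels, noise up to 1 uV,
#' amplitude and warp factors in `[0.8, 1.2]`.
#'
#' @param p_noise,p_dropout,p_amp,p_warp,p_reverse per-operator application
#'   probabilities in `[0, 1]`.
#' @param noise_std_range range of the Gaussian noise standard deviation (uV).
#' @param dropout_channels_range integer range of the number of channels hit
#'   by dropout.
#' @param dropout_len_range integer range of the dropout run length (samples).
#' @param amp_range range of the per-channel amplitude multiplier.
#' @param warp_range range of the time-axis resampling factor.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_noise = 0.5, noise_std_range = c(0, 1),
                           p_dropout = 0.7, dropout_channels_range = c(1, 8),
                           dropout_len_range = c(1, 1800),
                           p_amp = 0.5, amp_range = c(0.8, 1.2),
                           p_warp = 0.5, warp_range = c(0.8, 1.2),
                           p_reverse = 0.5) {
  for (p in c(p_noise, p_dropout, p_amp, p_warp, p_reverse)) {
    check_number(p, "probability", 0, 1)
  }
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(noise_std_range) || noise_std_range[1] < 0) {
    stopf("noise_std_range must be an ordered non-negative pair")
  }
  if (!rng_ok(dropout_channels_range) || dropout_channels_range[1] < 1) {
    stopf("dropout_channels_range must be an ordered pair of counts")
  }
  if (!rng_ok(dropout_len_range) || dropout_len_range[1] < 1) {
    stopf("dropout_len_range must be an ordered pair of counts")
  }
  if (!rng_ok(amp_range) || !rng_ok(warp_range)) {
    stopf("amp_range and warp_range must be ordered pairs")
  }
  structure(
    list(p_noise = p_noise, noise_std_range = as.numeric(noise_std_range),
         p_dropout = p_dropout,
         dropout_channels_range = as.integer(dropout_channels_range),
         dropout_len_range = as.integer(dropout_len_range),
         p_amp = p_amp, amp_range = as.numeric(amp_range),
         p_warp = p_warp, warp_range = as.numeric(warp_range),
         p_reverse = p_reverse),
    class = "augment_config"
  )
}

#' Apply stochastic augmentation to one segment
#'
#' See [augment_config()] for the five operators and their order. The output
#' always has the shape of the input. Augmentation is a training-time device:
#' it is never applied at validation, test or prediction time.
#'
#' @param segment_data numeric matrix `[n_channels x L]`.
#' @param cfg an [augment_config()].
#' @param seed optional integer; if given, the call is run under a local RNG
#'   state seeded with it (the caller's RNG stream is untouched). If `NULL`,
#'   draws come from the current RNG stream, so a seeded training loop
#'   remains reproducible end to end.
#' @return A numeric matrix of the same shape.
#' @export
augment_segment <- function(segment_data, cfg = augment_config(), seed = NULL) {
  stopifnot(is.matrix(segment_data), inherits(cfg, "augment_config"))
  C <- nrow(segment_data); L <- ncol(segment_data)
  if (L < cfg$dropout_len_range[2]) {
    stopf("segment length %d shorter than dropout_len_range max %d",
          L, cfg$dropout_len_range[2])
  }
  with_seed(seed, {
    x <- segment_data

    if (stats::runif(1) < cfg$p_noise) {
      std <- stats::runif(1, cfg$noise_std_range[1], cfg$noise_std_range[2])
      x <- x + matrix(stats::rnorm(C * L, sd = max(std, 1e-300)), C, L)
    }

    if (stats::runif(1) < cfg$p_dropout) {
      k_max <- cfg$dropout_channels_range[2]
      if (k_max > C) {
        warning(sprintf("dropout channel count clamped from %d to %d", k_max, C))
        k_max <- C
      }
      k_min <- min(cfg$dropout_channels_range[1], k_max)
      k <- sample(k_min:k_max, 1L)
      chans <- sample.int(C, k)
      for (ch in chans) {
        B <- sample(cfg$dropout_len_range[1]:cfg$dropout_len_range[2], 1L)
        start <- sample.int(L - B + 1L, 1L)
        x[ch, start:(start + B - 1L)] <- 0
      }
    }

    if (stats::runif(1) < cfg$p_amp) {
      m <- stats::runif(C, cfg$amp_range[1], cfg$amp_range[2])
      x <- x * m
    }

    if (stats::runif(1) < cfg$p_warp) {
      f <- stats::runif(1, cfg$warp_range[1], cfg$warp_range[2])
      x <- warp_time(x, f)
    }

    if (stats::runif(1) < cfg$p_reverse) {
      x <- x[, L:1, drop = FALSE]
    }

    x
  })
}

# Resample the time axis by factor f (linear interpolation to round(L*f)
# samples), then restore length L: center-crop when stretched, edge-pad with
# the boundary value when shrunk.
warp_time <- function(x, f) {
  L <- ncol(x)
  L2 <- max(2L, as.integer(round(L * f)))
  if (L2 == L) return(x)
  pos <- seq(1, L, length.out = L2)
  lo <- pmin(floor(pos), L - 1L)
  w <- pos - lo
  y <- x[, lo, drop = FALSE] * (1 - rep(w, each = nrow(x))) +
    x[, lo + 1L, drop = FALSE] * rep(w, each = nrow(x))
  if (L2 > L) {
    off <- (L2 - L) %/% 2L
    y[, (off + 1L):(off + L), drop = FALSE]
  } else {
    pad <- L - L2
    left <- pad %/% 2L
    right <- pad - left
    cbind(
      matrix(rep(y[, 1L], left), nrow = nrow(x)),
      y,
      matrix(rep(y[, L2], right), nrow = nrow(x))
    )
  }
}
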