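#' Integrated-gradients attribution for one segment
#'
#' Approximates the path integral of the model's input gradient from a
#' baseline to the input (midpoint Riemann sum over `n_steps` points),
#' scaled elementwise by `input - baseline`. The attribution satisfies the
#' completeness axiom: its sum converges to `model(input) - model(baseline)`
#' (raw network output, no clamping) as `n_steps` grows. The default
#' baseline is the all-zero tensor — absent EEG as the reference signal.
#'
#' @param model a trained [age_model()].
#' @param input the model input: a `[depth x C x L]` array, or a `[C x L]`
#'   segment matrix which is stacked automatically.
#' @param baseline same shape as the (stacked) input; default all zeros.
#' @param n_steps number of integration steps (>= 8).
#' @param meta optional named list carried on the map (e.g. `sex`,
#'   `eye_state`, `subject_id`) for downstream stratification.
#' @return An object of class `attribution_map`: `values` (array shaped like
#'   the stacked input), the metadata, and the model's channel-roll amount
#'   (needed to fold stack slices back onto source channels).
#' @export
integrated_gradients <- function(model, input, baseline = NULL,
                                 n_steps = 64L, meta = list()) {
  stopifnot(inherits(model, "age_model"))
  n_steps <- check_count(n_steps, "n_steps", min = 8L)
  cfg <- model$config
  if (is.matrix(input)) input <- stacked_transform(input, cfg$stack_depth)
  dims <- c(cfg$stack_depth, cfg$n_channels, cfg$seg_samples)
  if (!identical(dim(input), as.integer(dims))) {
    stopf("input shape (%s) does not match the model input (%s)",
          paste(dim(input), collapse = ", "), paste(dims, collapse = ", "))
  }
  if (is.null(baseline)) baseline <- array(0, dim = dims)
  if (is.matrix(baseline)) baseline <- stacked_transform(baseline,
                                                         cfg$stack_depth)
  if (!identical(dim(baseline), as.integer(dims))) {
    stopf("baseline shape (%s) does not match the input (%s)",
          paste(dim(baseline), collapse = ", "), paste(dims, collapse = ", "))
  }
  x <- as.vector(input)
  x0 <- as.vector(baseline)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  X <- vapply(alphas, function(a) x0 + a * (x - x0), numeric(length(x)))
  fwd <- forward_pass(model, X, training = FALSE, keep_cache = TRUE)
  grads <- backward_pass(model, fwd, rep(1, n_steps), training = FALSE,
                         need_input_grad = TRUE)
  avg_grad <- rowMeans(grads$input)
  values <- array(avg_grad * (x - x0), dim = dims)
  structure(
    list(values = values, meta = meta,
         roll = cfg$n_channels %/% cfg$stack_depth,
         channel_names = NULL),
    class = "attribution_map"
  )
}

#' SmoothGrad-averaged integrated gradients
#'
#' Averages [integrated_gradients()] maps over `n_samples` copies of the
#' input perturbed with additive Gaussian noise of standard deviation
#' `noise_std` times the input range, which sharpens noisy sensitivity maps.
#' With `noise_std = 0` the result equals the plain integrated gradients.
#'
#' @inheritParams integrated_gradients
#' @param n_samples number of noisy replicates (>= 1).
#' @param noise_std noise level as a fraction of the input amplitude range.
#' @param seed integer seed; the map is reproducible for a fixed seed.
#' @return An `attribution_map` (the average map).
#' @export
smooth_grad <- function(model, input, baseline = NULL, n_samples = 16L,
                        noise_std = 0.1, seed = 1L, n_steps = 64L,
                        meta = list()) {
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  check_number(noise_std, "noise_std", lower = 0)
  cfg <- model$config
  if (is.matrix(input)) input <- stacked_transform(input, cfg$stack_depth)
  sd_abs <- noise_std * (max(input) - min(input))
  maps <- with_seed(seed, {
    lapply(seq_len(n_samples), function(i) {
      noisy <- input +
        array(stats::rnorm(length(input), sd = sd_abs), dim = dim(input))
      integrated_gradients(model, noisy, baseline, n_steps = n_steps)$values
    })
  })
  structure(
    list(values = Reduce(`+`, maps) / n_samples, meta = meta,
         roll = cfg$n_channels %/% cfg$stack_depth, channel_names = NULL),
    class = "attribution_map"
  )
}

# fold a [depth x C x L] attribution onto the C source channels: stack
# slice j, row i came from source channel ((i-1) + j*roll) mod C + 1
fold_to_channels <- function(map) {
  v <- map$values
  depth <- dim(v)[1]; C <- dim(v)[2]
  per_row <- apply(abs(v), c(1, 2), sum) # [depth x C], time-summed
  score <- numeric(C)
  for (j in 0:(depth - 1L)) {
    src <- ((seq_len(C) - 1L + j * map$roll) %% C) + 1L
    score[src] <- score[src] + per_row[j + 1L, ]
  }
  score
}

#' Channel importance from attribution maps
#'
#' Per segment, sums absolute attribution over the time and stack axes
#' (stack slices are folded back onto their source channels first), giving
#' one non-negative score per EEG channel. Scores are accumulated per
#' stratum (e.g. eye state or sex, read from each map's metadata) and
#' summarized by median and interquartile range.
#'
#' @param maps a list of `attribution_map` objects.
#' @param stratify_by metadata key(s) to stratify on: `"eye_state"`,
#'   `"sex"`, or both. Maps lacking the key form no stratum and are an
#'   error.
#' @param channel_names optional channel labels.
#' @return An object of class `channel_importance`: `scores` (long data
#'   frame: stratum, channel, segment score) and `summary` (stratum x
#'   channel medians and IQRs). Strata with no segments are simply absent.
#' @export
channel_importance <- function(maps, stratify_by = "eye_state",
                               channel_names = NULL) {
  if (!length(maps)) stopf("no attribution maps given")
  stopifnot(all(vapply(maps, inherits, TRUE, "attribution_map")))
  allowed <- c("eye_state", "sex")
  if (!all(stratify_by %in% allowed)) {
    stopf("unknown stratification key(s): %s",
          paste(setdiff(stratify_by, allowed), collapse = ", "))
  }
  C <- dim(maps[[1]]$values)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  rows <- lapply(maps, function(m) {
    vals <- vapply(stratify_by, function(k) {
      v <- m$meta[[k]]
      if (is.null(v)) stopf("attribution map lacks metadata key '%s'", k)
      as.character(v)
    }, "")
    data.frame(stratum = paste(vals, collapse = "/"),
               channel = channel_names,
               score = fold_to_channels(m))
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  summ <- do.call(rbind, lapply(
    split(scores, list(scores$stratum, scores$channel), drop = TRUE),
    function(d) {
      # ECDF-based quantiles (type 2): summaries depend only on the score
      # distribution, not on how often each map is listed
      data.frame(stratum = d$stratum[1], channel = d$channel[1],
                 median = stats::median(d$score),
                 iqr = stats::IQR(d$score, type = 2), n = nrow(d))
    }))
  rownames(summ) <- NULL
  structure(
    list(scores = scores, summary = summ, stratify_by = stratify_by,
         channel_names = channel_names),
    class = "channel_importance"
  )
}

#' @export
print.channel_importance <- function(x, ...) {
  cat(sprintf("<channel_importance> %d channels, strata: %s\n",
              length(x$channel_names),
              paste(unique(x$summary$stratum), collapse = ", ")))
  top <- stats::aggregate(median ~ channel, data = x$summary, FUN = mean)
  top <- top[order(-top$median), ][seq_len(min(5, nrow(top))), ]
  cat("  top channels (mean median score):",
      paste(sprintf("%s (%.3g)", top$channel, top$median), collapse = ", "),
      "\n")
  invisible(x)
}

#' Eyes-open vs eyes-closed attribution difference
#'
#' For each channel, computes `D`, the absolute difference between the
#' median attribution scores under the two eye states, and flags the
#' channel when `D` exceeds twice the interquartile range of the
#' eyes-closed scores (strict inequality).
#'
#' @param importance a [channel_importance()] stratified by `eye_state`.
#' @return A data frame: `channel`, `median_eo`, `median_ec`, `iqr_ec`,
#'   `D`, `flagged`.
#' @export
eye_state_difference <- function(importance) {
  stopifnot(inherits(importance, "channel_importance"))
  s <- importance$summary
  if (!all(c("EO", "EC") %in% unique(s$stratum))) {
    stopf("both eye states must be present (stratify_by = 'eye_state')")
  }
  out <- do.call(rbind, lapply(importance$channel_names, function(ch) {
    eo <- s[s$stratum == "EO" & s$channel == ch, ]
    ec <- s[s$stratum == "EC" & s$channel == ch, ]
    if (!nrow(eo) || !nrow(ec)) {
      stopf("channel %s lacks one of the eye states", ch)
    }
    D <- abs(eo$median - ec$median)
    data.frame(channel = ch, median_eo = eo$median, median_ec = ec$median,
               iqr_ec = ec$iqr, D = D, flagged = D > 2 * ec$iqr)
  }))
  rownames(out) <- NULL
  out
}
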