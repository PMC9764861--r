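#' Segment-length sweep
#'
#' Longer segments give the network more context per sample but lose more
#' data to artifact rejection (an artifact anywhere in a window discards the
#' whole window). This harness retrains the model for each candidate segment
#' duration and reports, per duration, the number of surviving segments and
#' the upper 95% confidence bound of the cross-validated session-level MAE;
#' the optimum is the duration minimizing that bound. Windows overlap with
#' the given step; a 1-s candidate is cut without overlap (step = length).
#'
#' @param sessions list of [eeg_session()] objects.
#' @param candidate_lengths segment durations to try, in seconds.
#' @param step_s step between window starts in seconds.
#' @param n_folds number of cross-validation folds.
#' @param iterations which fold iterations to train per candidate (fewer
#'   than `n_folds` gives a cheaper unbiased subset).
#' @param model_cfg_fn function(seg_samples) returning the [model_config()]
#'   for a given segment length in samples, so the architecture can adapt to
#'   the duration.
#' @param train_cfg a [train_config()].
#' @param augment_cfg an [augment_config()] or `NULL`.
#' @param seed seed for the fold shuffle.
#' @return A data frame with one row per candidate: `seg_len_s`,
#'   `n_segments`, `mae_ci95_upper`, `feasible`, plus the attribute
#'   `optimal` (the feasible `seg_len_s` minimizing `mae_ci95_upper`).
#' @export
seglen_sweep <- function(sessions, candidate_lengths, step_s = 1,
                         n_folds = 10, iterations = seq_len(n_folds),
                         model_cfg_fn,
                         train_cfg = train_config(),
                         augment_cfg = NULL, seed = 1L) {
  stopifnot(is.list(sessions), length(candidate_lengths) >= 1)
  rows <- list()
  for (len in candidate_lengths) {
    step <- if (abs(len - 1) < 1e-12) len else step_s
    seg_list <- lapply(sessions, segment_session, seg_len_s = len,
                       step_s = step)
    counts <- vapply(seg_list, n_segments, 0L)
    total <- sum(counts)
    if (total == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        seg_len_s = len, n_segments = 0L, mae_ci95_upper = NA_real_,
        feasible = FALSE)
      next
    }
    segs <- bind_segments(seg_list)
    plan <- make_folds(segs, n_folds = n_folds, seed = seed)
    cv <- cross_validate(segs, plan, iterations = iterations,
                         model_cfg = model_cfg_fn(dim(segs$data)[2]),
                         train_cfg = train_cfg, augment_cfg = augment_cfg)
    ci <- if (nrow(cv$folds) >= 2) ci95_upper(cv$folds$test_mae) else
      mean(cv$folds$test_mae)
    rows[[length(rows) + 1L]] <- data.frame(
      seg_len_s = len, n_segments = total, mae_ci95_upper = ci,
      feasible = TRUE)
  }
  out <- do.call(rbind, rows)
  feas <- out[out$feasible, ]
  attr(out, "optimal") <- if (nrow(feas)) {
    feas$seg_len_s[which.min(feas$mae_ci95_upper)]
  } else NA_real_
  out
}
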