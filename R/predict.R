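#' Session-level age prediction
#'
#' Applies the model to every artifact-free segment of one session block and
#' averages: the session age is the arithmetic mean of the per-segment
#' predictions (each clamped at 0).
#'
#' @param model a trained [age_model()].
#' @param segments an `eeg_segments` object containing the segments of
#'   exactly one session block (one `session_id` / `eye_state` pair).
#' @return An object of class `session_prediction`: a list with
#'   `subject_id`, `session_id`, `eye_state`, `segment_ages`, `session_age`,
#'   `n_segments`, `true_age`.
#' @export
predict_session <- function(model, segments) {
  stopifnot(inherits(segments, "eeg_segments"))
  if (n_segments(segments) == 0L) stopf("no artifact-free segments")
  key <- unique(paste(segments$meta$session_id, segments$meta$eye_state))
  if (length(key) != 1L) {
    stopf("segments span %d session blocks; predict_session expects one",
          length(key))
  }
  seg_ages <- predict(model, segments)
  structure(
    list(subject_id = segments$meta$subject_id[1],
         session_id = segments$meta$session_id[1],
         eye_state = segments$meta$eye_state[1],
         segment_ages = seg_ages,
         session_age = mean(seg_ages),
         n_segments = length(seg_ages),
         true_age = segments$meta$age_years[1]),
    class = "session_prediction"
  )
}

#' @export
print.session_prediction <- function(x, ...) {
  cat(sprintf(
    "<session_prediction> %s %s (%s): predicted %.1f y from %d segments (true %.1f y)\n",
    x$subject_id, x$session_id, x$eye_state, x$session_age, x$n_segments,
    x$true_age))
  invisible(x)
}

#' Predict every session block in a segment set
#'
#' @param model a trained [age_model()].
#' @param segments an `eeg_segments` object (any number of sessions).
#' @return A data frame with one row per session block: `subject_id`,
#'   `session_id`, `eye_state`, `n_segments`, `true_age`, `predicted_age`.
#' @export
predict_sessions <- function(model, segments) {
  stopifnot(inherits(segments, "eeg_segments"))
  if (n_segments(segments) == 0L) stopf("no artifact-free segments")
  pred <- predict(model, segments)
  key <- paste(segments$meta$session_id, segments$meta$eye_state)
  idx <- split(seq_along(pred), key)
  rows <- lapply(idx, function(i) {
    data.frame(
      subject_id = segments$meta$subject_id[i[1]],
      session_id = segments$meta$session_id[i[1]],
      eye_state = segments$meta$eye_state[i[1]],
      n_segments = length(i),
      true_age = segments$meta$age_years[i[1]],
      predicted_age = mean(pred[i])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subject-level prediction across eye states
#'
#' Pools the per-segment predictions of a subject's sessions. With
#' `mode = "both"` all segments of the eyes-open and eyes-closed blocks are
#' pooled before averaging (equivalent to the segment-count-weighted mean of
#' the session predictions); `"eo"`/`"ec"` restrict to one eye state.
#'
#' @param predictions a list of [predict_session()] results belonging to one
#'   subject.
#' @param mode `"both"`, `"eo"` or `"ec"`.
#' @return A single predicted age (years).
#' @export
predict_subject <- function(predictions, mode = c("both", "eo", "ec")) {
  mode <- match.arg(mode)
  if (inherits(predictions, "session_prediction")) {
    predictions <- list(predictions)
  }
  stopifnot(all(vapply(predictions, inherits, TRUE, "session_prediction")))
  subj <- unique(vapply(predictions, `[[`, "", "subject_id"))
  if (length(subj) != 1L) {
    stopf("predictions belong to %d subjects; expected one", length(subj))
  }
  wanted <- switch(mode, both = c("EO", "EC"), eo = "EO", ec = "EC")
  sel <- predictions[vapply(predictions, `[[`, "", "eye_state") %in% wanted]
  present <- unique(vapply(sel, `[[`, "", "eye_state"))
  missing <- setdiff(wanted, present)
  if (length(missing)) {
    stopf("requested eye state(s) absent: %s", paste(missing, collapse = ", "))
  }
  mean(unlist(lapply(sel, `[[`, "segment_ages")))
}

#' Evaluate session-level predictions
#'
#' Computes the headline metrics at session level: MAE, the coefficient of
#' determination, and the Pearson correlation between true and predicted
#' ages. If a fold/iteration column is present, a per-fold MAE table and its
#' upper 95% confidence bound are included.
#'
#' @param predictions a data frame as returned by [predict_sessions()]
#'   (optionally with an `iteration` column), or the `predictions` element
#'   of an `age_cv` object.
#' @return An object of class `age_eval`.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("true_age", "predicted_age") %in% names(predictions)))
  if (nrow(predictions) < 2L) stopf("need at least 2 sessions to evaluate")
  y <- predictions$true_age
  yh <- predictions$predicted_age
  r2 <- if (stats::sd(y) > 0) r_squared(y, yh) else NA_real_
  r <- if (stats::sd(y) > 0 && stats::sd(yh) > 0) stats::cor(y, yh) else
    NA_real_
  per_fold <- NULL
  ci <- NA_real_
  if ("iteration" %in% names(predictions)) {
    per_fold <- do.call(rbind, lapply(
      split(predictions, predictions$iteration), function(d) {
        data.frame(iteration = d$iteration[1],
                   mae = mae(d$true_age, d$predicted_age),
                   n_sessions = nrow(d))
      }))
    rownames(per_fold) <- NULL
    if (nrow(per_fold) >= 2) ci <- ci95_upper(per_fold$mae)
  }
  structure(
    list(mae = mae(y, yh), r_squared = r2, pearson_r = r,
         per_fold = per_fold, mae_ci95_upper = ci,
         n_sessions = nrow(predictions)),
    class = "age_eval"
  )
}

#' @export
print.age_eval <- function(x, ...) {
  cat(sprintf("<age_eval> %d sessions\n  MAE %.2f years", x$n_sessions, x$mae))
  if (!is.na(x$r_squared)) cat(sprintf(", R2 %.2f", x$r_squared))
  if (!is.na(x$pearson_r)) cat(sprintf(", Pearson r %.2f", x$pearson_r))
  cat("\n")
  if (!is.null(x$per_fold)) {
    cat(sprintf("  per-fold MAE: %s\n",
                paste(sprintf("%.2f", x$per_fold$mae), collapse = ", ")))
    if (!is.na(x$mae_ci95_upper)) {
      cat(sprintf("  CI95 upper bound: %.2f years\n", x$mae_ci95_upper))
    }
  }
  invisible(x)
}

#' Eye-state experiment matrix
#'
#' Evaluates models trained on different eye-state subsets (both, eyes open
#' only, eyes closed only) on every test modality, producing the 3 x 3 MAE
#' table of the eye-state experiment. Rows are training modality, columns
#' test modality; each cell is the session-level MAE on the test segments
#' restricted to that modality (cells whose test modality has no segments
#' are `NA`).
#'
#' @param models named list with elements `both`, `eo`, `ec`: trained
#'   [age_model()]s.
#' @param test_segments an `eeg_segments` object with both eye states.
#' @return A 3 x 3 numeric matrix with dimnames
#'   `train = c("both","eo","ec")` x `test = c("both","eo","ec")`.
#' @export
eye_state_matrix <- function(models, test_segments) {
  stopifnot(all(c("both", "eo", "ec") %in% names(models)))
  modes <- c("both", "eo", "ec")
  out <- matrix(NA_real_, 3, 3, dimnames = list(train = modes, test = modes))
  for (tr in modes) {
    for (te in modes) {
      wanted <- switch(te, both = c("EO", "EC"), eo = "EO", ec = "EC")
      sel <- which(test_segments$meta$eye_state %in% wanted)
      if (!length(sel)) next
      preds <- predict_sessions(models[[tr]], test_segments[sel])
      out[tr, te] <- mae(preds$true_age, preds$predicted_age)
    }
  }
  out
}
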