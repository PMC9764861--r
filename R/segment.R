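#' Cut a session into overlapping artifact-free segments
#'
#' Candidate windows of `seg_len_s` seconds start at `0, step_s, 2*step_s,
#' ...` seconds from block onset while they fit inside the block (half-open
#' windows `[start, start + L)` in samples), giving
#' `floor((T - L)/step) + 1` candidates for a clean block. Any window that
#' contains at least one masked sample is discarded — the strictest reading
#' of artifact rejection, so surviving segments are guaranteed artifact-free.
#'
#' @param session an [eeg_session()].
#' @param seg_len_s segment length in seconds.
#' @param step_s step between consecutive window starts in seconds.
#' @return An `eeg_segments` object: a list with `data`, a
#'   `[n_channels x L x n_segments]` array, and `meta`, a data frame with one
#'   row per segment (`subject_id`, `session_id`, `eye_state`, `age_years`,
#'   `sex`, `start_sample` 0-based). Zero surviving segments is a valid
#'   result, not an error.
#' @export
segment_session <- function(session, seg_len_s = 5, step_s = 1) {
  stopifnot(inherits(session, "eeg_session"))
  check_number(seg_len_s, "seg_len_s", lower = 1e-9)
  check_number(step_s, "step_s", lower = 1e-9)
  fs <- session$sampling_rate_hz
  L <- as.integer(round(seg_len_s * fs))
  step <- as.integer(round(step_s * fs))
  if (L < 1L || step < 1L) stopf("segment or step shorter than one sample")
  n <- ncol(session$signal)
  starts <- integer(0)
  if (n >= L) starts <- seq.int(0L, n - L, by = step)
  # discard any window that touches a masked sample
  if (length(starts) && any(session$mask)) {
    bad <- cumsum(session$mask) # masked samples among first k samples
    keep <- vapply(starts, function(s) {
      bad[s + L] - (if (s > 0L) bad[s] else 0L) == 0L
    }, TRUE)
    starts <- starts[keep]
  }
  data <- array(0, dim = c(nrow(session$signal), L, length(starts)))
  for (j in seq_along(starts)) {
    data[, , j] <- session$signal[, (starts[j] + 1L):(starts[j] + L)]
  }
  meta <- data.frame(
    subject_id = rep(session$subject_id, length(starts)),
    session_id = rep(session$session_id, length(starts)),
    eye_state = rep(session$eye_state, length(starts)),
    age_years = rep(session$age_years, length(starts)),
    sex = rep(session$sex, length(starts)),
    start_sample = as.integer(starts),
    stringsAsFactors = FALSE
  )
  new_segments(data, meta, session$channel_names, fs)
}

new_segments <- function(data, meta, channel_names, sampling_rate_hz) {
  structure(
    list(data = data, meta = meta, channel_names = channel_names,
         sampling_rate_hz = sampling_rate_hz),
    class = "eeg_segments"
  )
}

#' Combine segment sets from several sessions
#'
#' @param ... `eeg_segments` objects with identical channel layout and
#'   sampling rate (or a single list of them).
#' @return One pooled `eeg_segments` object.
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "eeg_segments")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, TRUE, "eeg_segments")))
  parts <- parts[vapply(parts, n_segments, 0L) > 0L]
  if (!length(parts)) stopf("no segments to combine")
  ref <- parts[[1]]
  dims <- vapply(parts, function(p) dim(p$data)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("segment sets have differing channel counts or lengths")
  }
  data <- array(0, dim = c(dim(ref$data)[1:2], sum(vapply(parts, n_segments, 0L))))
  at <- 0L
  for (p in parts) {
    k <- n_segments(p)
    data[, , (at + 1L):(at + k)] <- p$data
    at <- at + k
  }
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  new_segments(data, meta, ref$channel_names, ref$sampling_rate_hz)
}

#' Number of segments in an `eeg_segments` object
#' @param segments an `eeg_segments` object.
#' @return Integer count.
#' @export
n_segments <- function(segments) {
  stopifnot(inherits(segments, "eeg_segments"))
  nrow(segments$meta)
}

#' Subset segments by index
#' @param x an `eeg_segments` object.
#' @param i integer or logical index over segments.
#' @param ... unused.
#' @return An `eeg_segments` object with the selected segments.
#' @export
`[.eeg_segments` <- function(x, i, ...) {
  new_segments(x$data[, , i, drop = FALSE], x$meta[i, , drop = FALSE],
               x$channel_names, x$sampling_rate_hz)
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf(
    "<eeg_segments> %d segments of %d channels x %d samples (%d subjects, %d sessions)\n",
    n_segments(x), dim(x$data)[1], dim(x$data)[2],
    length(unique(x$meta$subject_id)),
    length(unique(paste(x$meta$session_id, x$meta$eye_state)))))
  invisible(x)
}
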