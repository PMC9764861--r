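#' Construct an EEG session
#'
#' One resting-state recording block: a channels-by-samples signal matrix in
#' microvolts, a per-sample artifact mask, and the metadata the age model
#' needs (subject, age at recording time, sex, eye state).
#'
#' @param signal numeric matrix `[n_channels x n_samples]`, amplitudes in uV.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param subject_id,session_id character identifiers.
#' @param eye_state `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @param age_years subject age in years at recording time, in `[0, 130]`.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param channel_names character vector of 10-10 labels, one per row of
#'   `signal`.
#' @param mask logical vector with one element per sample; `TRUE` marks an
#'   artifact-contaminated sample. Defaults to all clean.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(signal, sampling_rate_hz, subject_id, session_id,
                        eye_state, age_years, sex = "unknown",
                        channel_names = NULL,
                        mask = rep(FALSE, ncol(signal))) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stopf("'signal' must be a numeric matrix [channels x samples]")
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(signal)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(nrow(signal)))
    }
  }
  if (length(channel_names) != nrow(signal)) {
    stopf("length(channel_names) (%d) != nrow(signal) (%d)",
          length(channel_names), nrow(signal))
  }
  if (length(mask) != ncol(signal)) {
    stopf("mask length (%d) != number of samples (%d)",
          length(mask), ncol(signal))
  }
  eye_state <- match.arg(eye_state, c("EO", "EC"))
  sex <- match.arg(sex, c("female", "male", "unknown"))
  check_number(age_years, "age_years", 0, 130)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  rownames(signal) <- channel_names
  structure(
    list(
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      eye_state = eye_state,
      age_years = as.numeric(age_years),
      sex = sex,
      signal = signal,
      mask = as.logical(mask),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      channel_names = as.character(channel_names)
    ),
    class = "eeg_session"
  )
}

#' @export
print.eeg_session <- function(x, ...) {
  dur <- ncol(x$signal) / x$sampling_rate_hz
  cat(sprintf(
    "<eeg_session> subject %s, session %s (%s)\n  %d channels x %d samples (%.1f s @ %g Hz), %.1f%% masked\n  age %.1f y, sex %s\n",
    x$subject_id, x$session_id, x$eye_state, nrow(x$signal), ncol(x$signal),
    dur, x$sampling_rate_hz, 100 * mean(x$mask), x$age_years, x$sex))
  invisible(x)
}

# run-length encode a logical mask as half-open [start, end) 0-based pairs
mask_to_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

runs_to_mask <- function(runs, n) {
  mask <- rep(FALSE, n)
  if (length(runs)) {
    runs <- matrix(as.numeric(runs), ncol = 2)
    for (i in seq_len(nrow(runs))) {
      if (runs[i, 2] > runs[i, 1]) mask[(runs[i, 1] + 1):runs[i, 2]] <- TRUE
    }
  }
  mask
}
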