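#' Zero-phase band-pass and notch filtering
#'
#' Applies a zero-phase Butterworth band-pass (an order-2 high-pass cascade
#' with an order-4 low-pass, each run forward and backward with
#' [signal::filtfilt()]) and, optionally, an order-2 band-stop of +/- 1 Hz
#' around the mains frequency. The artifact mask is left untouched; filtering
#' never creates or removes artifact marks.
#'
#' @param session an [eeg_session()].
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < rate/2`.
#' @param notch_hz mains frequency to remove (`50` or `60`), or `NULL` for
#'   none.
#' @return The filtered [eeg_session()].
#' @export
bandpass_notch <- function(session, low_hz = 0.5, high_hz = 100,
                           notch_hz = NULL) {
  stopifnot(inherits(session, "eeg_session"))
  nyq <- session$sampling_rate_hz / 2
  check_number(low_hz, "low_hz", lower = 1e-9)
  check_number(high_hz, "high_hz")
  if (low_hz >= high_hz) stopf("low_hz (%g) must be below high_hz (%g)",
                               low_hz, high_hz)
  if (high_hz >= nyq) stopf("high_hz (%g) must be below Nyquist (%g Hz)",
                            high_hz, nyq)
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  bs <- NULL
  if (!is.null(notch_hz)) {
    notch_hz <- check_number(notch_hz, "notch_hz", lower = 1)
    if (notch_hz + 1 >= nyq) stopf("notch frequency too close to Nyquist")
    bs <- signal::butter(2, c(notch_hz - 1, notch_hz + 1) / nyq, type = "stop")
  }
  out <- session$signal
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(hp, out[i, ])
    x <- signal::filtfilt(lp, x)
    if (!is.null(bs)) x <- signal::filtfilt(bs, x)
    out[i, ] <- x
  }
  session$signal <- out
  session
}
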