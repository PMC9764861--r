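# Welch PSD over the artifact-free stretches of a session: Hann-windowed
# half-overlapping windows of window_s seconds, one-sided density in
# uV^2/Hz. Returns freqs and a [freq x channel] matrix.
welch_psd <- function(session, window_s = 2) {
  fs <- session$sampling_rate_hz
  nwin <- as.integer(round(window_s * fs))
  clean <- segment_session(session, seg_len_s = window_s,
                           step_s = window_s / 2)
  if (n_segments(clean) == 0L) stopf("no artifact-free data for band power")
  n_ch <- nrow(session$signal)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  half <- seq_len(nwin %/% 2 + 1L)
  freqs <- (half - 1L) * fs / nwin
  one_sided <- rep(2, length(half))
  one_sided[1] <- 1
  if (nwin %% 2 == 0) one_sided[length(half)] <- 1
  # all (window, channel) columns in a single FFT call
  nW <- n_segments(clean)
  cols <- matrix(0, nrow = nwin, ncol = nW * n_ch)
  for (j in seq_len(nW)) {
    seg <- matrix(clean$data[, , j], nrow = n_ch)
    cols[, ((j - 1L) * n_ch + 1L):(j * n_ch)] <- t(seg - rowMeans(seg)) * w
  }
  spec <- stats::mvfft(cols)
  p2 <- Mod(spec[half, , drop = FALSE])^2
  dim(p2) <- c(length(half), n_ch, nW)
  acc <- rowSums(p2, dims = 2)
  psd <- acc * (scale / nW) * one_sided
  colnames(psd) <- session$channel_names
  list(freqs = freqs, psd = psd, df = fs / nwin)
}

#' Absolute band power per channel
#'
#' Estimates the power spectral density of each channel by an averaged
#' periodogram (Welch's method: Hann-windowed windows of `window_s` seconds
#' with 50% overlap, cut from the artifact-free stretches of the session)
#' and integrates it across the band. Units are uV^2.
#'
#' @param session an [eeg_session()].
#' @param band numeric `[low_hz, high_hz]` inside `(0, rate/2)`.
#' @param window_s periodogram window length in seconds.
#' @return Named numeric vector, one power per channel.
#' @export
band_power <- function(session, band, window_s = 2) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$sampling_rate_hz
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    stopf("band must be [low, high] inside (0, Nyquist)")
  }
  wp <- welch_psd(session, window_s)
  sel <- wp$freqs >= band[1] & wp$freqs <= band[2]
  stats::setNames(colSums(wp$psd[sel, , drop = FALSE]) * wp$df,
                  session$channel_names)
}

#' Session-level band power table
#'
#' Computes one Welch PSD per session and integrates it over every requested
#' band, avoiding repeated spectral estimation when several bands (or a
#' permutation null) are screened.
#'
#' @inheritParams age_correlation_screen
#' @return A long data frame: `session`, `subject_id`, `eye_state`,
#'   `age_years`, `channel`, `band`, `power`.
#' @export
band_power_table <- function(sessions, bands = EEG_BANDS, window_s = 2) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    wp <- welch_psd(s, window_s)
    per_band <- lapply(names(bands), function(b) {
      sel <- wp$freqs >= bands[[b]][1] & wp$freqs <= bands[[b]][2]
      data.frame(session = i, subject_id = s$subject_id,
                 eye_state = s$eye_state, age_years = s$age_years,
                 channel = s$channel_names, band = b,
                 power = colSums(wp$psd[sel, , drop = FALSE]) * wp$df)
    })
    rows[[i]] <- do.call(rbind, per_band)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Band-power vs age correlation screen
#'
#' For every (channel, band, eye state) cell, correlates session-level
#' absolute band power with age across sessions using Spearman's rank
#' correlation, then applies Benjamini-Hochberg false-discovery-rate
#' correction jointly across all cells of the screen and flags cells with
#' `q < alpha`. This is the sanity screen run before any model training: an
#' age signal that a network could exploit must show up here as systematic
#' (typically negative) correlations.
#'
#' @param sessions list of [eeg_session()] objects.
#' @param bands named list of `[low, high]` band edges (default: delta
#'   1-4, theta 4-7, alpha 8-12, beta 12-30 Hz).
#' @param eye_states eye states to screen.
#' @param alpha FDR level for the significance flag.
#' @param window_s periodogram window passed to [band_power()].
#' @param power_table optional precomputed [band_power_table()]; pass it to
#'   rescreen the same spectra (e.g. under permuted ages) without
#'   recomputing PSDs.
#' @param ages optional replacement age vector, one entry per session in
#'   `sessions`/`power_table` order, used for permutation-null calibration.
#' @return A data frame of class `band_power_screen`: `channel`, `band`,
#'   `eye_state`, `rho`, `p_value`, `q_value`, `significant`. Cells with
#'   constant power (undefined rank correlation) carry `NA` and are excluded
#'   from the correction family.
#' @export
age_correlation_screen <- function(sessions = NULL, bands = EEG_BANDS,
                                   eye_states = c("EO", "EC"),
                                   alpha = 0.05, window_s = 2,
                                   power_table = NULL, ages = NULL) {
  if (is.null(power_table)) {
    if (is.null(sessions)) stopf("either sessions or power_table is required")
    power_table <- band_power_table(sessions, bands, window_s)
  }
  if (!is.null(ages)) {
    power_table$age_years <- ages[power_table$session]
  }
  rows <- list()
  for (st in eye_states) {
    tab <- power_table[power_table$eye_state == st, ]
    if (length(unique(tab$session)) < 10L) {
      stopf("need at least 10 sessions for eye state %s, got %d",
            st, length(unique(tab$session)))
    }
    for (b in unique(tab$band)) {
      bt <- tab[tab$band == b, ]
      for (ch in unique(bt$channel)) {
        cell <- bt[bt$channel == ch, ]
        if (stats::sd(cell$power) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            channel = ch, band = b, eye_state = st, rho = NA_real_,
            p_value = NA_real_)
          next
        }
        ct <- suppressWarnings(
          stats::cor.test(cell$age_years, cell$power, method = "spearman",
                          exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, band = b, eye_state = st,
          rho = unname(ct$estimate), p_value = ct$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  class(out) <- c("band_power_screen", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.band_power_screen <- function(x, ...) {
  cat(sprintf(
    "<band_power_screen> %d cells, %d significant at FDR %g\n",
    nrow(x), sum(x$significant), attr(x, "alpha")))
  for (b in unique(x$band)) {
    sub <- x[x$band == b & !is.na(x$rho), ]
    cat(sprintf("  %-6s median rho %+.2f, %d/%d significant\n", b,
                stats::median(sub$rho), sum(sub$significant), nrow(sub)))
  }
  invisible(x)
}
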