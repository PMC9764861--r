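# Minimal European Data Format (EDF) support: 16-bit signals, one data record
# per second. Enough to exchange single-block resting-state sessions with
# standard EEG software; not a general EDF+ implementation (no annotations,
# no discontinuous records).
#
# Conventions used by this package:
#   * patient field:   "id=<subject_id> sex=<female|male|unknown> age=<years>"
#   * recording field: "session=<session_id> eye=<EO|EC>"
#   * the artifact mask travels as an extra 0/1 signal labelled "MASK"
#   * signal physical dimension must be uV, mV or V; anything else is an error
#     (never a silent rescale)

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

# render a number into <= 8 ASCII chars without losing the magnitude
num_field <- function(x) {
  vapply(x, function(v) {
    for (fmt in c("%.6g", "%.4g", "%.2e", "%.1e")) {
      s <- sprintf(fmt, v)
      if (nchar(s) <= 8) return(s)
    }
    sprintf("%.0e", v)
  }, "")
}

#' Write an EEG session as an EDF file
#'
#' The signal is quantized to 16 bits per channel with per-channel physical
#' scaling; the artifact mask is stored as an additional 0/1 signal labelled
#' `MASK`, and the session metadata is encoded in the EDF patient and
#' recording header fields (see the package conventions in [read_edf()]).
#' The recording is truncated to a whole number of seconds.
#'
#' @param session an [eeg_session()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$sampling_rate_hz
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  n_rec <- ncol(session$signal) %/% fs
  if (n_rec < 1L) stopf("session shorter than one EDF record (1 s)")
  keep <- seq_len(n_rec * fs)
  sig <- session$signal[, keep, drop = FALSE]
  mask_num <- as.numeric(session$mask[keep])
  ns <- nrow(sig) + 1L # + mask channel

  # per-channel physical range, symmetric, strictly positive width; the 1%
  # headroom guarantees the range still covers the data after the 8-char
  # header rendering, and both writer and reader quantize against the
  # parsed-back header strings so their scaling agrees exactly
  pmax_v <- pmax(apply(abs(sig), 1, max), 1e-6) * 1.01
  pmin_str <- num_field(-pmax_v)
  pmax_str <- num_field(pmax_v)
  dig_min <- -32768; dig_max <- 32767

  header <- paste0(
    pad_field("0", 8),
    pad_field(sprintf("id=%s sex=%s age=%g",
                      session$subject_id, session$sex, session$age_years), 80),
    pad_field(sprintf("session=%s eye=%s",
                      session$session_id, session$eye_state), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (1L + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  labels <- c(session$channel_names, "MASK")
  dims <- c(rep("uV", nrow(sig)), "")
  phys_min <- c(as.numeric(pmin_str), 0)
  phys_max <- c(as.numeric(pmax_str), 1)
  dmin <- c(rep(dig_min, nrow(sig)), 0)
  dmax <- c(rep(dig_max, nrow(sig)), 1)
  sig_header <- paste0(
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(vapply(dims, pad_field, "", width = 8), collapse = ""),
    paste(vapply(num_field(phys_min), pad_field, "", width = 8), collapse = ""),
    paste(vapply(num_field(phys_max), pad_field, "", width = 8), collapse = ""),
    paste(vapply(dmin, pad_field, "", width = 8), collapse = ""),
    paste(vapply(dmax, pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )

  # digitize: value -> dig units
  dig <- matrix(0L, nrow = ns, ncol = n_rec * fs)
  for (i in seq_len(nrow(sig))) {
    scale <- (dig_max - dig_min) / (phys_max[i] - phys_min[i])
    d <- round((sig[i, ] - phys_min[i]) * scale) + dig_min
    dig[i, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  dig[ns, ] <- as.integer(mask_num)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig_header), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_header_field <- function(raw_hdr, offset, width) {
  trimws(rawToChar(raw_hdr[(offset + 1):(offset + width)]))
}

parse_kv <- function(text, key) {
  m <- regmatches(text, regexec(paste0(key, "=(\\S+)"), text))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Read an EDF file as an EEG session
#'
#' Signals declared in volts or millivolts are converted to microvolts; an
#' unrecognized physical dimension on an EEG channel is an error, never a
#' silent rescale. A signal labelled `MASK` populates the artifact mask
#' (values > 0.5 mark artifact samples) and is excluded from the signal
#' matrix. Subject metadata is parsed from `key=value` entries in the patient
#' (`id`, `sex`, `age`) and recording (`session`, `eye`) header fields; a
#' missing age is a hard error because it is the regression target.
#'
#' @param path an EDF file.
#' @return An [eeg_session()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  patient <- read_header_field(hdr, 8, 80)
  recording <- read_header_field(hdr, 88, 80)
  n_rec <- as.integer(read_header_field(hdr, 236, 8))
  rec_dur <- as.numeric(read_header_field(hdr, 244, 8))
  ns <- as.integer(read_header_field(hdr, 252, 4))

  shdr <- readBin(con, "raw", 256L * ns)
  fld <- function(offset, width, i) {
    read_header_field(shdr, offset * ns + (i - 1L) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), "")
  dims <- vapply(seq_len(ns), function(i) fld(96, 8, i), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) fld(104, 8, i), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) fld(112, 8, i), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) fld(120, 8, i), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) fld(128, 8, i), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i) fld(216, 8, i), ""))

  if (length(unique(spr)) != 1L) {
    stopf("EDF signals with differing sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  n_samples <- n_rec * spr[1]

  raw_vals <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                      signed = TRUE, endian = "little")
  if (length(raw_vals) != n_rec * sum(spr)) stopf("EDF file %s truncated", path)
  dat <- matrix(NA_real_, nrow = ns, ncol = n_samples)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- raw_vals[(pos + 1L):(pos + spr[i])]
      pos <- pos + spr[i]
      phys <- (vals - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      dat[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }

  is_mask <- toupper(labels) == "MASK"
  mask <- if (any(is_mask)) dat[which(is_mask)[1], ] > 0.5 else
    rep(FALSE, n_samples)
  sig_idx <- which(!is_mask)
  signal <- dat[sig_idx, , drop = FALSE]
  for (j in seq_along(sig_idx)) {
    unit <- dims[sig_idx[j]]
    mult <- switch(tolower(unit), "uv" = 1, "µv" = 1, "mv" = 1e3,
                   "v" = 1e6, NULL)
    if (is.null(mult)) {
      stopf("channel %s declares ambiguous unit '%s'; expected uV, mV or V",
            labels[sig_idx[j]], unit)
    }
    signal[j, ] <- signal[j, ] * mult
  }

  age <- suppressWarnings(as.numeric(parse_kv(patient, "age")))
  if (is.na(age)) stopf("missing metadata: age_years")
  sex <- parse_kv(patient, "sex")
  if (is.na(sex)) sex <- "unknown"
  subj <- parse_kv(patient, "id")
  if (is.na(subj)) subj <- "unknown"
  sess <- parse_kv(recording, "session")
  if (is.na(sess)) sess <- "unknown"
  eye <- parse_kv(recording, "eye")
  if (is.na(eye) || !eye %in% c("EO", "EC")) {
    stopf("missing metadata: eye_state")
  }
  eeg_session(signal, fs, subj, sess, eye, age, sex,
              channel_names = labels[sig_idx], mask = mask)
}
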