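#' Read or write an EEG session
#'
#' Two on-disk formats are supported. The native *store* format is a raw
#' little-endian 32-bit float matrix (row-major, channels x samples, uV) at
#' `path` plus a JSON metadata sidecar at `paste0(path, ".json")` holding the
#' subject/session metadata and the artifact mask as half-open `[start, end)`
#' sample runs. The *edf* format is the 16-bit European Data Format; see
#' [read_edf()] for how metadata and the mask channel are carried.
#'
#' @param session an [eeg_session()].
#' @param path file path. For `format = "store"` the sidecar lives at
#'   `paste0(path, ".json")`.
#' @param format `"store"` or `"edf"`.
#' @return `read_session()` returns an [eeg_session()]; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path, format = c("store", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "eeg_session"))
  if (format == "edf") return(write_edf(session, path))
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major: each channel's samples contiguous
  writeBin(as.vector(t(session$signal)), con, size = 4L, endian = "little")
  meta <- list(
    subject_id = session$subject_id,
    session_id = session$session_id,
    eye_state = session$eye_state,
    age_years = session$age_years,
    sex = session$sex,
    sampling_rate_hz = session$sampling_rate_hz,
    channel_names = session$channel_names,
    n_samples = ncol(session$signal),
    mask_runs = mask_to_runs(session$mask)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, format = c("store", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stopf("no such file: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing metadata sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("subject_id", "session_id", "eye_state", "age_years", "sex",
                "sampling_rate_hz", "channel_names", "n_samples")
  absent <- setdiff(required, names(meta))
  if (length(absent)) stopf("missing metadata: %s", paste(absent, collapse = ", "))
  n_ch <- length(meta$channel_names)
  n_s <- as.integer(meta$n_samples)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_ch * n_s, size = 4L, endian = "little")
  if (length(vals) != n_ch * n_s) {
    stopf("store file %s truncated: expected %d values, read %d",
          path, n_ch * n_s, length(vals))
  }
  signal <- matrix(vals, nrow = n_ch, ncol = n_s, byrow = TRUE)
  mask <- runs_to_mask(meta$mask_runs, n_s)
  eeg_session(signal, meta$sampling_rate_hz, meta$subject_id, meta$session_id,
              meta$eye_state, meta$age_years, meta$sex,
              channel_names = meta$channel_names, mask = mask)
}
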