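#' Specification of a synthetic resting-state EEG cohort
#'
#' Describes a cohort shaped like a clinical lifespan EEG archive: 26-channel
#' 10-10 recordings at 500 Hz, two 2-minute blocks per subject (eyes open and
#' eyes closed), ages spanning 5-88 years, an artifact mask channel, and --
#' the property the age model must learn -- band power that declines with
#' age. Each channel is a sum of a 1/f background and band-limited Gaussian
#' oscillations (delta 1-4, theta 4-7, alpha 8-12, beta 12-30 Hz) whose RMS
#' amplitudes scale log-linearly with age,
#' \eqn{a_b(age) = a_{b,0}\,e^{s_b (age - age_{min})}}, so that a negative
#' per-year slope \eqn{s_b} yields a monotone decline of band power with age.
#' Alpha amplitude is raised in the eyes-closed block (the Berger effect).
#'
#' @param n_subjects number of subjects.
#' @param age_range numeric `[min, max]` in years; ages are drawn uniformly.
#' @param n_channels number of EEG channels (10-10 labels are assigned for up
#'   to 26 channels).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param block_seconds duration of each eye-state block in seconds.
#' @param band_slopes named numeric vector, per-year fractional amplitude
#'   change per band (negative = decline with age).
#' @param band_amp_uv named numeric vector, baseline RMS amplitude per band in
#'   uV at the youngest age.
#' @param noise_floor_uv RMS amplitude of the broadband 1/f background in uV.
#' @param alpha_ec_boost multiplicative alpha amplitude factor for the
#'   eyes-closed block (> 1).
#' @param artifact_rate_per_min expected number of injected high-amplitude
#'   transient artifacts per minute per block.
#' @param fingerprint_strength number in `[0, 1]`: standard deviation of a
#'   per-subject log-amplitude spectral tilt applied identically to all of
#'   that subject's data. Non-zero values give each subject a recognizable
#'   spectral idiosyncrasy, which is what a segment-level random
#'   cross-validation split can exploit (the data-leakage demonstration).
#' @param subject_sd lognormal sigma of per-subject, per-band amplitude
#'   variability unrelated to age.
#' @param informative_channels optional integer vector: synthesize the
#'   band-limited oscillations (and hence the age code) only on these
#'   channels, leaving all others with the bare 1/f background. `NULL`
#'   (default) encodes age in every channel. Used by attribution
#'   experiments, where the question is whether channel importance recovers
#'   the channel that carries the signal.
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bit for bit.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200,
                        age_range = c(5, 88),
                        n_channels = 26,
                        sampling_rate_hz = 500,
                        block_seconds = 120,
                        band_slopes = c(delta = -0.015, theta = -0.012,
                                        alpha = -0.010, beta = -0.006),
                        band_amp_uv = c(delta = 8, theta = 6,
                                        alpha = 10, beta = 4),
                        noise_floor_uv = 2,
                        alpha_ec_boost = 1.8,
                        artifact_rate_per_min = 2,
                        fingerprint_strength = 0,
                        subject_sd = 0.1,
                        informative_channels = NULL,
                        seed = 1L) {
  check_count(n_subjects, "n_subjects")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stopf("age_range must be [min, max] with min < max")
  }
  check_count(n_channels, "n_channels")
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_number(block_seconds, "block_seconds", lower = 1e-9)
  bands <- names(EEG_BANDS)
  if (!all(bands %in% names(band_slopes))) {
    stopf("band_slopes must name all of: %s", paste(bands, collapse = ", "))
  }
  if (!all(bands %in% names(band_amp_uv))) {
    stopf("band_amp_uv must name all of: %s", paste(bands, collapse = ", "))
  }
  top_edge <- max(vapply(EEG_BANDS, max, 0))
  if (sampling_rate_hz <= 2 * top_edge) {
    stopf("sampling_rate_hz must exceed twice the highest band edge (%g Hz)",
          top_edge)
  }
  check_number(noise_floor_uv, "noise_floor_uv", lower = 0)
  check_number(alpha_ec_boost, "alpha_ec_boost", lower = 1)
  check_number(artifact_rate_per_min, "artifact_rate_per_min", lower = 0)
  check_number(fingerprint_strength, "fingerprint_strength", 0, 1)
  check_number(subject_sd, "subject_sd", lower = 0)
  if (!is.null(informative_channels)) {
    informative_channels <- as.integer(informative_channels)
    if (any(informative_channels < 1 | informative_channels > n_channels)) {
      stopf("informative_channels out of range")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
         n_channels = as.integer(n_channels),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         block_seconds = as.numeric(block_seconds),
         band_slopes = band_slopes[bands], band_amp_uv = band_amp_uv[bands],
         noise_floor_uv = noise_floor_uv, alpha_ec_boost = alpha_ec_boost,
         artifact_rate_per_min = artifact_rate_per_min,
         fingerprint_strength = fingerprint_strength, subject_sd = subject_sd,
         informative_channels = informative_channels, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# One EEG block for all channels in a single inverse FFT. Each channel is a
# Gaussian process whose power spectrum is the sum of a 1/f background (RMS
# `floor_uv`) and flat in-band components with per-channel RMS amplitudes
# `band_amps` (a band x channel matrix); a sum of independent Gaussian
# processes is itself Gaussian with the summed spectrum. For a spectral
# amplitude scale s_f on k bins, the realized RMS^2 is sum(s_f^2)/n^2, which
# fixes the normalization below; realized band power then fluctuates around
# its target like any finite sample of a random process.
synth_block <- function(n_ch, n, fs, floor_uv, band_amps) {
  freqs <- (0:(n - 1)) * fs / n
  f_fold <- pmin(freqs, fs - freqs)
  pink <- ifelse(f_fold >= 0.5, 1 / f_fold, 0)
  pink <- pink / sum(pink) # normalized power profile
  s2 <- matrix(floor_uv^2 * n^2 * pink, nrow = n, ncol = n_ch)
  for (b in rownames(band_amps)) {
    edges <- EEG_BANDS[[b]]
    sel <- f_fold >= edges[1] & f_fold <= edges[2]
    k <- sum(sel)
    s2[sel, ] <- s2[sel, ] +
      rep(band_amps[b, ]^2 * n^2 / k, each = k)
  }
  z <- matrix(complex(real = stats::rnorm(n * n_ch),
                      imaginary = stats::rnorm(n * n_ch)),
              nrow = n, ncol = n_ch)
  x <- Re(stats::mvfft(z * sqrt(s2), inverse = TRUE)) / n
  t(x)
}

#' Generate a synthetic EEG cohort
#'
#' Produces two [eeg_session()] blocks (eyes open, eyes closed) per subject
#' according to a [cohort_spec()]. High-amplitude transient artifacts
#' (0.5-2 s, ten times the channel RMS, on 1-4 random channels) are injected
#' at the configured rate and marked in the session mask over their full
#' extent; the ground-truth artifact sample runs are attached to each session
#' as the `injected_artifacts` attribute (a two-column matrix of half-open
#' 0-based `[start, end)` pairs).
#'
#' @param spec a [cohort_spec()].
#' @param callback optional `function(session, index)`. When given, each
#'   session is passed to the callback as soon as it is generated and *not*
#'   retained, and the list of callback results is returned instead. Use
#'   this to stream large cohorts (a full-scale 200-subject cohort holds
#'   several GB of signal) through a reducer such as [band_power_table()]
#'   without materializing them. The generated signals are identical either
#'   way for the same spec.
#' @return A list of `eeg_session` objects, two per subject (sessions of the
#'   same subject share a `session_id`); with a `callback`, the list of its
#'   return values in the same order.
#' @export
generate_cohort <- function(spec, callback = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    fs <- spec$sampling_rate_hz
    nsamp <- as.integer(round(spec$block_seconds * fs))
    bands <- names(EEG_BANDS)
    ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sexes <- sample(c("female", "male"), n, replace = TRUE)
    ch_names <- if (spec$n_channels <= length(CHANNELS_26)) {
      CHANNELS_26[seq_len(spec$n_channels)]
    } else {
      paste0("ch", seq_len(spec$n_channels))
    }
    sessions <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      subj <- sprintf("sub-%04d", i)
      # age-independent per-subject amplitude idiosyncrasies
      indiv <- exp(spec$subject_sd * stats::rnorm(length(bands)))
      tilt <- exp(spec$fingerprint_strength * stats::rnorm(length(bands)))
      names(indiv) <- names(tilt) <- bands
      for (state in c("EO", "EC")) {
        band_amps <- matrix(0, nrow = length(bands), ncol = spec$n_channels,
                            dimnames = list(bands, NULL))
        for (b in bands) {
          amp_young <- spec$band_amp_uv[[b]] * indiv[[b]] * tilt[[b]]
          amp_aged <- amp_young *
            exp(spec$band_slopes[[b]] * (ages[i] - spec$age_range[1]))
          amp <- rep(amp_aged, spec$n_channels)
          if (!is.null(spec$informative_channels)) {
            # band oscillations only on the informative channels; the rest
            # carry just the 1/f background
            amp <- rep(0, spec$n_channels)
            amp[spec$informative_channels] <- amp_aged
          }
          if (b == "alpha" && state == "EC") amp <- amp * spec$alpha_ec_boost
          band_amps[b, ] <- amp
        }
        sig <- synth_block(spec$n_channels, nsamp, fs, spec$noise_floor_uv,
                           band_amps)
        # transient artifacts: 0.5-2 s at 10x channel RMS on 1-4 channels
        mask <- rep(FALSE, nsamp)
        runs <- matrix(numeric(0), ncol = 2)
        n_art <- stats::rpois(1, spec$artifact_rate_per_min *
                                spec$block_seconds / 60)
        for (a in seq_len(n_art)) {
          len <- as.integer(round(stats::runif(1, 0.5, 2) * fs))
          len <- min(len, nsamp)
          start <- sample.int(nsamp - len + 1L, 1L) - 1L
          idx <- (start + 1L):(start + len)
          k <- sample.int(min(4L, spec$n_channels), 1L)
          chans <- sample.int(spec$n_channels, k)
          for (ch in chans) {
            rms <- sqrt(mean(sig[ch, ]^2))
            bump <- 10 * rms * sin(pi * seq_along(idx) / length(idx))
            sig[ch, idx] <- sig[ch, idx] + bump
          }
          mask[idx] <- TRUE
          runs <- rbind(runs, c(start, start + len))
        }
        s <- eeg_session(sig, fs, subj, paste0(subj, "_ses1"), state,
                         ages[i], sexes[i], channel_names = ch_names,
                         mask = mask)
        attr(s, "injected_artifacts") <- runs
        k <- 2L * (i - 1L) + (state == "EC") + 1L
        sessions[[k]] <- if (is.null(callback)) s else callback(s, k)
      }
    }
    sessions
  })
}
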