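# periodogram-based band power oracle, independent of the package's Welch
# estimator: raw |FFT|^2 integrated over the band
oracle_band_power <- function(signal_row, fs, band) {
  n <- length(signal_row)
  sp <- Mod(stats::fft(signal_row))^2 / (fs * n)
  freqs <- (0:(n - 1)) * fs / n
  half <- seq_len(n %/% 2 + 1)
  sel <- freqs[half] >= band[1] & freqs[half] <= band[2]
  2 * sum(sp[half][sel]) * fs / n
}

small_spec <- function(artifact_rate_per_min = 0, seed = 77, ...) {
  cohort_spec(n_subjects = 40, n_channels = 4, sampling_rate_hz = 100,
              block_seconds = 8,
              artifact_rate_per_min = artifact_rate_per_min, seed = seed, ...)
}

test_that("identical spec and seed reproduce the cohort bit for bit", {
  s1 <- generate_cohort(small_spec(artifact_rate_per_min = 3))
  s2 <- generate_cohort(small_spec(artifact_rate_per_min = 3))
  expect_identical(lapply(s1, `[[`, "signal"), lapply(s2, `[[`, "signal"))
  expect_identical(lapply(s1, `[[`, "mask"), lapply(s2, `[[`, "mask"))
  s3 <- generate_cohort(small_spec(artifact_rate_per_min = 3, seed = 78))
  expect_false(identical(s1[[1]]$signal, s3[[1]]$signal))
})

test_that("cohort structure matches the spec", {
  sess <- generate_cohort(small_spec())
  expect_length(sess, 80) # two blocks per subject
  states <- vapply(sess, `[[`, "", "eye_state")
  expect_equal(sum(states == "EO"), 40)
  subjects <- vapply(sess, `[[`, "", "subject_id")
  expect_true(all(table(subjects) == 2))
  ages <- vapply(sess, `[[`, 0, "age_years")
  expect_true(all(ages >= 5 & ages <= 88))
  expect_equal(ncol(sess[[1]]$signal), 800)
})

test_that("negative alpha slope induces negative age correlation everywhere", {
  sess <- generate_cohort(cohort_spec(
    n_subjects = 60, n_channels = 4, sampling_rate_hz = 100,
    block_seconds = 8, artifact_rate_per_min = 0, subject_sd = 0.05,
    seed = 31))
  eo <- Filter(function(s) s$eye_state == "EO", sess)
  ages <- vapply(eo, `[[`, 0, "age_years")
  for (ch in 1:4) {
    pw <- vapply(eo, function(s)
      oracle_band_power(s$signal[ch, ], 100, c(8, 12)), 0)
    expect_lt(cor(ages, pw, method = "spearman"), 0)
  }
})

test_that("zero slopes and zero fingerprint give no age signal", {
  sess <- generate_cohort(cohort_spec(
    n_subjects = 200, n_channels = 2, sampling_rate_hz = 100,
    block_seconds = 4, artifact_rate_per_min = 0,
    band_slopes = c(delta = 0, theta = 0, alpha = 0, beta = 0),
    subject_sd = 0.05, fingerprint_strength = 0, seed = 57))
  eo <- Filter(function(s) s$eye_state == "EO", sess)
  ages <- vapply(eo, `[[`, 0, "age_years")
  pw <- vapply(eo, function(s)
    oracle_band_power(s$signal[1, ], 100, c(8, 12)), 0)
  rho <- cor(ages, pw, method = "spearman")
  # critical value of |rho| at alpha = 0.05, n = 200
  expect_lt(abs(rho), 1.96 / sqrt(199))
})

test_that("band power declines monotonically across age terciles", {
  sess <- generate_cohort(cohort_spec(
    n_subjects = 90, n_channels = 3, sampling_rate_hz = 100,
    block_seconds = 8, artifact_rate_per_min = 0, subject_sd = 0.03,
    seed = 91))
  eo <- Filter(function(s) s$eye_state == "EO", sess)
  ages <- vapply(eo, `[[`, 0, "age_years")
  terc <- cut(ages, quantile(ages, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  for (band in list(c(1, 4), c(4, 7), c(8, 12), c(12, 30))) {
    for (ch in 1:3) {
      pw <- vapply(eo, function(s)
        oracle_band_power(s$signal[ch, ], 100, band), 0)
      expect_lt(median(pw[terc == 3]), median(pw[terc == 1]))
    }
  }
})

test_that("eyes-closed alpha exceeds eyes-open alpha for every subject", {
  sess <- generate_cohort(small_spec())
  subjects <- vapply(sess, `[[`, "", "subject_id")
  states <- vapply(sess, `[[`, "", "eye_state")
  for (subj in unique(subjects)) {
    eo <- sess[[which(subjects == subj & states == "EO")]]
    ec <- sess[[which(subjects == subj & states == "EC")]]
    a_eo <- mean(vapply(1:4, function(ch)
      oracle_band_power(eo$signal[ch, ], 100, c(8, 12)), 0))
    a_ec <- mean(vapply(1:4, function(ch)
      oracle_band_power(ec$signal[ch, ], 100, c(8, 12)), 0))
    expect_gt(a_ec, a_eo)
  }
})

test_that("every injected artifact is masked and nothing else is", {
  sess <- generate_cohort(small_spec(artifact_rate_per_min = 6))
  n_with <- 0
  for (s in sess) {
    runs <- attr(s, "injected_artifacts")
    truth <- eegage:::runs_to_mask(runs, ncol(s$signal))
    expect_identical(s$mask, truth)
    if (nrow(runs) > 0) n_with <- n_with + 1
  }
  expect_gt(n_with, 0)
})

test_that("informative-channel restriction localizes the age signal", {
  sess <- generate_cohort(cohort_spec(
    n_subjects = 80, n_channels = 4, sampling_rate_hz = 100,
    block_seconds = 8, artifact_rate_per_min = 0, subject_sd = 0.05,
    informative_channels = 2L, seed = 19))
  eo <- Filter(function(s) s$eye_state == "EO", sess)
  ages <- vapply(eo, `[[`, 0, "age_years")
  rhos <- vapply(1:4, function(ch) {
    pw <- vapply(eo, function(s)
      oracle_band_power(s$signal[ch, ], 100, c(1, 4)), 0)
    cor(ages, pw, method = "spearman")
  }, 0)
  expect_lt(rhos[2], -0.8)
  expect_true(all(abs(rhos[-2]) < 0.4))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(cohort_spec(age_range = c(50, 10)), "age_range")
  expect_error(cohort_spec(sampling_rate_hz = 50), "twice the highest")
  expect_error(cohort_spec(informative_channels = 40), "out of range")
})
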