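# Shared fixtures, built lazily once per test run and cached. Heavy objects
# (trained models) are reused across test files to keep the suite fast.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

# free a heavy fixture once the last test that needs it has run
drop_fixture <- function(...) {
  for (name in c(...)) fixture_cache[[name]] <- NULL
  invisible(gc(verbose = FALSE))
}

# desk-scale study conditions: 8 channels, 250 Hz, 12-s blocks, strong
# age-dependent power decline, subject-specific spectral fingerprints
desk_spec <- function(n_subjects = 300, seed = 421, ...) {
  cohort_spec(
    n_subjects = n_subjects, n_channels = 8, sampling_rate_hz = 250,
    block_seconds = 12, artifact_rate_per_min = 1,
    band_slopes = c(delta = -0.03, theta = -0.02, alpha = -0.025,
                    beta = -0.015),
    fingerprint_strength = 0.5, seed = seed, ...
  )
}

desk_train_config <- function(...) {
  train_config(lr = 3e-3, batch_size = 64, max_epochs = 6, seed = 11, ...)
}

desk_augment_config <- function() {
  augment_config(dropout_len_range = c(1, 400))
}

# a small clean session for IO/filter/segmentation unit tests
toy_session <- function(n_ch = 4, seconds = 10, fs = 100, seed = 99,
                        mask = NULL, age = 33.5) {
  sig <- with_toy_seed(seed, matrix(stats::rnorm(n_ch * seconds * fs, sd = 3),
                                    nrow = n_ch))
  if (is.null(mask)) mask <- rep(FALSE, ncol(sig))
  eeg_session(sig, fs, "sub-toy", "sub-toy_ses1", "EO", age, "female",
              channel_names = paste0("ch", seq_len(n_ch)), mask = mask)
}

with_toy_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# the 300-subject training cohort shared by the heavy acceptance tests
desk_cohort <- function() fixture("desk_cohort", function() {
  generate_cohort(desk_spec())
})

desk_segments <- function() fixture("desk_segments", function() {
  bind_segments(lapply(desk_cohort(), segment_session,
                       seg_len_s = 2, step_s = 2))
})

desk_plan <- function() fixture("desk_plan", function() {
  make_folds(desk_segments(), n_folds = 10, seed = 5)
})

# cross-subject training run (shared by parameter-recovery and leakage tests)
desk_fit_cross <- function() fixture("desk_fit_cross", function() {
  train_age_model(desk_segments(), desk_plan(), 1, model_preset("tiny"),
                  desk_train_config(), desk_augment_config())
})

# session-level MAE of the constant mean-age predictor on a segment subset
mean_predictor_mae <- function(segments, idx, train_idx) {
  sub <- segments[idx]
  key <- paste(sub$meta$session_id, sub$meta$eye_state)
  true_age <- tapply(sub$meta$age_years, key, function(a) a[1])
  mae(as.vector(true_age),
      rep(mean(segments$meta$age_years[train_idx]), length(true_age)))
}
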