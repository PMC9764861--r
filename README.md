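# eegage

Brain age prediction from raw resting-state scalp EEG.

EEG spectral power declines systematically across the human lifespan, and
that decline carries enough information to estimate a person's
chronological age from a few minutes of resting-state recording. `eegage`
implements the full pipeline for doing so with a deep convolutional
regressor, for researchers who want an age estimator (or its gap to the
chronological age, the *brain-PAD* candidate biomarker) from standard
26-channel 10-10 recordings:

* **Model.** A raw segment `[channels x time]` is expanded into a *stacked
  tensor* — four copies with channel rows cyclically rolled by
  `j * floor(C/4)` — and passed through four blocks of (valid 2-D
  convolution, batch norm, SiLU) with kernels (7,64), (7,32), (7,16),
  (7,8), stride (1,3), widths 16-128, then global average pooling and a
  linear head. Per-segment predictions `Age_si >= 0` are averaged into the
  session prediction `Age_s = (1/N_s) * sum_i Age_si`.
* **Training.** Segment-level MAE or the relative MALE loss
  `mean(|log(y+1) - log(yhat+1)|)`, Adam, reduce-on-plateau, early
  stopping, under 10-fold **cross-subject** cross-validation: all
  eyes-open and eyes-closed segments of a subject stay in one fold. A
  segment-level random split is included only to demonstrate how badly
  leakage inflates validation metrics.
* **Around the model.** Synthetic lifespan cohorts with a controllable
  spectral age code (so everything is testable without any restricted
  archive); EDF and binary session IO; zero-phase band-pass/notch
  filtering; overlapping segmentation with artifact rejection; five
  stochastic augmentation operators; a segment-length sweep; optimal
  age-group boundaries by differential evolution under a 2x class-balance
  constraint; integrated-gradients channel attribution with SmoothGrad;
  and a band-power/age Spearman screen with FDR correction.

The network — including backpropagation and input gradients — is
implemented in base R on BLAS matrix products; there is no deep-learning
framework dependency. See `vignette("brain-age-eeg")` for the model,
design decisions, and limitations.

## Worked example

Generate a desk-scale synthetic cohort in which band power declines with
age, train the small architecture preset under cross-subject
cross-validation, and evaluate at session level:

```r
library(eegage)

spec <- cohort_spec(n_subjects = 100, n_channels = 8,
                    sampling_rate_hz = 250, block_seconds = 16,
                    artifact_rate_per_min = 1,
                    band_slopes = c(delta = -0.03, theta = -0.02,
                                    alpha = -0.025, beta = -0.015),
                    seed = 7)
sessions <- generate_cohort(spec)          # 2 blocks (EO, EC) per subject
segs <- bind_segments(lapply(sessions, segment_session,
                             seg_len_s = 2, step_s = 2))
segs
#> <eeg_segments> 1508 segments of 8 channels x 500 samples (100 subjects, 200 sessions)

plan <- make_folds(segs, n_folds = 5, seed = 1)
fit <- train_age_model(segs, plan, iteration = 1,
                       model_cfg = model_preset("tiny"),
                       train_cfg = train_config(lr = 3e-3, batch_size = 64,
                                                max_epochs = 8, seed = 2),
                       augment_cfg = augment_config(
                         dropout_len_range = c(1, 400)))
tail(fit$history, 3)
#>   epoch train_loss  val_mae    lr
#> 6     6   8.983057 8.195941 0.003
#> 7     7   7.006093 9.448705 0.003
#> 8     8   6.481132 3.621461 0.003
```

The history shows the segment-level training loss and the session-level
validation MAE in years: after eight epochs the model predicts held-out
subjects' ages to a few years, against roughly 20 years for the constant
mean-age predictor. Evaluate the held-out test fold and inspect the
metrics:

```r
preds <- predict_sessions(fit, segs[fit$split$test])
evaluate_predictions(preds)
#> <age_eval> 40 sessions
#>   MAE 4.45 years, R2 0.93, Pearson r 0.98
```

Each row of `preds` is one session block with its pooled prediction;
`predict_subject()` pools a subject's EO and EC segments, and
`optimize_boundaries(preds$true_age, preds$predicted_age, K = 3)` finds
the age grouping that the predictions separate best. A command-line front
end with `simulate`, `segment`, `bandpower`, `train` and `groups`
subcommands is installed at `inst/scripts/eegage`.

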