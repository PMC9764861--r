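# micro-scale study: 4 channels, 100 Hz, strong age encoding; trains in
# seconds and is reused by several training behaviour tests
micro_spec <- function(n_subjects = 80, seed = 611, ...) {
  cohort_spec(n_subjects = n_subjects, n_channels = 4,
              sampling_rate_hz = 100, block_seconds = 10,
              artifact_rate_per_min = 0.5, subject_sd = 0.05,
              band_slopes = c(delta = -0.03, theta = -0.02, alpha = -0.025,
                              beta = -0.015),
              seed = seed, ...)
}

micro_model_cfg <- function(seg_samples = 200) {
  model_config(n_channels = 4, seg_samples = seg_samples, stack_depth = 4,
               conv_kernels = list(c(2, 8), c(2, 4), c(1, 4), c(1, 4)),
               conv_stride = c(1, 2), conv_widths = c(8, 16, 32, 64))
}

micro_augment <- function() {
  augment_config(dropout_len_range = c(1, 150),
                 dropout_channels_range = c(1, 3))
}

micro_segments <- function() fixture("micro_segments", function() {
  bind_segments(lapply(generate_cohort(micro_spec()), segment_session,
                       seg_len_s = 2, step_s = 2))
})

test_that("max_epochs 0 returns the initialized model without error", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  fit <- train_age_model(segs, plan, 1, micro_model_cfg(),
                         train_config(max_epochs = 0, seed = 1),
                         micro_augment())
  expect_false(fit$trained)
  expect_equal(nrow(fit$history), 0)
})

test_that("training is deterministic for fixed seeds", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  cfg <- train_config(lr = 3e-3, batch_size = 64, max_epochs = 2, seed = 7)
  f1 <- train_age_model(segs, plan, 1, micro_model_cfg(), cfg,
                        micro_augment())
  f2 <- train_age_model(segs, plan, 1, micro_model_cfg(), cfg,
                        micro_augment())
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training reduces validation error below the mean predictor", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  fit <- train_age_model(segs, plan, 1, micro_model_cfg(),
                         train_config(lr = 3e-3, batch_size = 64,
                                      max_epochs = 4, seed = 3),
                         micro_augment())
  base <- mean_predictor_mae(segs, fit$split$val, fit$split$train)
  expect_lt(min(fit$history$val_mae), base)
  # the returned model carries the best epoch's parameters
  expect_equal(session_mae <- eegage:::session_level_mae(fit, segs,
                                                         fit$split$val),
               min(fit$history$val_mae), tolerance = 1e-9)
})

test_that("no validation or test subject is seen by the optimizer", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  for (it in 1:5) {
    sp <- resolve_split(plan, segs, it)
    train_subj <- unique(segs$meta$subject_id[sp$train])
    held_subj <- unique(segs$meta$subject_id[c(sp$val, sp$test)])
    expect_length(intersect(train_subj, held_subj), 0)
  }
})

test_that("relative-loss training favours the youngest tercile", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  young_mae <- function(loss, seed) {
    fit <- train_age_model(segs, plan, 1, micro_model_cfg(),
                           train_config(loss = loss, lr = 3e-3,
                                        batch_size = 64, max_epochs = 4,
                                        seed = seed),
                           micro_augment())
    preds <- predict_sessions(fit, segs[fit$split$test])
    terc <- quantile(preds$true_age, 1 / 3)
    young <- preds[preds$true_age <= terc, ]
    mae(young$true_age, young$predicted_age)
  }
  seeds <- c(31, 32, 33)
  m_abs <- vapply(seeds, function(s) young_mae("mae", s), 0)
  m_rel <- vapply(seeds, function(s) young_mae("male", s), 0)
  expect_lt(mean(m_rel), mean(m_abs))
})

test_that("training on both eye states beats matched single-state models", {
  # the alpha rhythm differs between eye states; models trained on one
  # state see half the data and a narrower input distribution, so the
  # both-states model should match or beat each single-state model on its
  # own modality (assessed over 3 seeds)
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  tabs <- lapply(41:43, function(seed) {
    models <- lapply(c(both = "both", eo = "eo", ec = "ec"), function(mode) {
      wanted <- switch(mode, both = c("EO", "EC"), eo = "EO", ec = "EC")
      sub <- segs[segs$meta$eye_state %in% wanted]
      train_age_model(sub, plan, 1, micro_model_cfg(),
                      train_config(lr = 3e-3, batch_size = 64,
                                   max_epochs = 4, seed = seed),
                      micro_augment())
    })
    test_idx <- eegage:::resolve_split(plan, segs, 1)$test
    eye_state_matrix(models, segs[test_idx])
  })
  m <- function(tr, te) mean(vapply(tabs, function(t) t[tr, te], 0))
  expect_lte(m("both", "both"), m("eo", "eo") + 1)
  expect_lte(m("both", "both"), m("ec", "ec") + 1)
  # every cell of every matrix is a finite MAE
  for (t in tabs) expect_true(all(is.finite(t)))
})

test_that("cross_validate aggregates per-fold test metrics", {
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  cv <- cross_validate(segs, plan, iterations = 1:2, micro_model_cfg(),
                       train_config(lr = 3e-3, batch_size = 64,
                                    max_epochs = 2, seed = 5),
                       micro_augment())
  expect_equal(nrow(cv$folds), 2)
  expect_true(all(cv$folds$test_mae > 0))
  ev <- evaluate_predictions(cv$predictions)
  expect_s3_class(ev, "age_eval")
  expect_equal(nrow(ev$per_fold), 2)
  # test sets of different iterations cover different subjects
  s1 <- unique(cv$predictions$subject_id[cv$predictions$iteration == 1])
  s2 <- unique(cv$predictions$subject_id[cv$predictions$iteration == 2])
  expect_length(intersect(s1, s2), 0)
})

test_that("plateau scheduling and early stopping govern the run", {
  # train to convergence: the validation MAE plateaus, the learning rate
  # must then drop by the scheduler factor, and training must stop before
  # max_epochs once the early-stopping patience is exhausted
  segs <- micro_segments()
  plan <- make_folds(segs, 5, seed = 2)
  fit <- train_age_model(segs, plan, 1, micro_model_cfg(),
                         train_config(lr = 3e-3, batch_size = 64,
                                      max_epochs = 30, scheduler_patience = 2,
                                      early_stop_patience = 6, seed = 5),
                         NULL)
  h <- fit$history
  expect_lt(nrow(h), 30) # early stop fired
  lrs <- unique(h$lr)
  expect_gt(length(lrs), 1) # scheduler fired
  expect_equal(lrs[2], lrs[1] * 0.1, tolerance = 1e-12)
  best_epoch <- h$epoch[which.min(h$val_mae)]
  expect_equal(nrow(h), best_epoch + 6) # stopped after 6 stalls
  expect_equal(fit$best_epoch, best_epoch)
})
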