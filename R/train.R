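#' Training configuration
#'
#' @param loss `"mae"` (absolute) or `"male"` (relative, log-ratio) segment
#'   loss. The relative loss weighs a fixed age *ratio* equally across the
#'   lifespan, improving accuracy for young subjects at a small cost in the
#'   oldest group.
#' @param lr starting learning rate of the Adam optimizer.
#' @param batch_size training batch size in segments.
#' @param scheduler_patience epochs without validation improvement before the
#'   learning rate is multiplied by `scheduler_factor` (reduce-on-plateau).
#' @param scheduler_factor learning-rate reduction factor.
#' @param early_stop_patience epochs without validation improvement before
#'   training stops.
#' @param max_epochs safety bound on the number of epochs.
#' @param seed integer seed covering weight initialization, batch shuffling
#'   and augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("mae", "male"), lr = 3e-4,
                         batch_size = 512L, scheduler_patience = 3L,
                         scheduler_factor = 0.1, early_stop_patience = 10L,
                         max_epochs = 100L, seed = 1L) {
  loss <- match.arg(loss)
  check_number(lr, "lr", lower = 1e-12)
  check_count(batch_size, "batch_size")
  check_count(scheduler_patience, "scheduler_patience")
  check_number(scheduler_factor, "scheduler_factor", lower = 1e-9, upper = 1)
  check_count(early_stop_patience, "early_stop_patience")
  check_count(max_epochs, "max_epochs", min = 0L)
  structure(
    list(loss = loss, lr = lr, batch_size = as.integer(batch_size),
         scheduler_patience = as.integer(scheduler_patience),
         scheduler_factor = scheduler_factor,
         early_stop_patience = as.integer(early_stop_patience),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
    class = "train_config"
  )
}

# segment-level loss value and gradient wrt predictions
loss_value_grad <- function(loss, y, yhat, eps = 1e-6) {
  n <- length(y)
  if (loss == "mae") {
    list(value = mean(abs(y - yhat)), grad = sign(yhat - y) / n)
  } else {
    shifted <- pmax(yhat + 1, eps)
    d <- log(shifted) - log(y + 1)
    g <- sign(d) / (n * shifted)
    g[yhat + 1 < eps] <- 0
    list(value = mean(abs(d)), grad = g)
  }
}

# session-level MAE of model predictions on a segment subset: per-segment
# predictions are averaged within each session block before the error
session_level_mae <- function(model, segments, idx) {
  sub <- segments[idx]
  pred <- predict(model, sub)
  key <- paste(sub$meta$session_id, sub$meta$eye_state)
  sess_pred <- tapply(pred, key, mean)
  sess_true <- tapply(sub$meta$age_years, key, function(a) a[1])
  mae(as.vector(sess_true), as.vector(sess_pred[names(sess_true)]))
}

#' Fit the convolutional age regressor
#'
#' Trains on the training folds of one cross-validation iteration,
#' minimizing the configured segment-level loss with Adam on augmented
#' segments. After each epoch the session-level validation MAE is computed
#' (in evaluation mode, without augmentation); the learning rate is reduced
#' on plateau, training stops early after `early_stop_patience`
#' non-improving epochs, and the returned model carries the parameters of
#' the best validation epoch together with the full epoch history.
#'
#' @param segments an `eeg_segments` object with all subjects' segments.
#' @param plan a [make_folds()] or [make_random_split()] plan.
#' @param iteration which cross-validation iteration (1-based) to train.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param augment_cfg an [augment_config()], or `NULL` to train without
#'   augmentation (the ablation configuration).
#' @return A trained [age_model()] with `$history` (one row per epoch:
#'   training loss, validation MAE, learning rate) and `$split` (the segment
#'   indices used for train/validation/test).
#' @export
train_age_model <- function(segments, plan, iteration = 1L,
                            model_cfg = model_preset("tiny"),
                            train_cfg = train_config(),
                            augment_cfg = augment_config()) {
  stopifnot(inherits(segments, "eeg_segments"))
  split <- resolve_split(plan, segments, iteration)
  if (!is.null(augment_cfg) &&
      augment_cfg$dropout_len_range[2] > model_cfg$seg_samples) {
    # keep dropout runs inside the segment for short desk-scale segments
    augment_cfg$dropout_len_range[2] <- model_cfg$seg_samples
  }
  model <- age_model(model_cfg, seed = train_cfg$seed)
  ages <- segments$meta$age_years
  if (length(split$train)) {
    # start the output at the training-set mean age: the network then only
    # has to learn deviations from it, which makes desk-scale training with
    # few optimizer steps converge (standard regression-head initialization)
    model$params$b_head <- mean(ages[split$train])
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mae = numeric(), lr = numeric())
  if (train_cfg$max_epochs == 0L) {
    model$history <- history
    model$split <- split
    return(model)
  }
  if (!length(split$train)) stopf("empty training fold")
  if (!length(split$val)) stopf("empty validation fold")

  opt <- adam_init(model$params)
  lr <- train_cfg$lr
  best <- list(mae = Inf, params = model$params, bn = model$bn, epoch = 0L)
  stall <- 0L

  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      order_idx <- sample(split$train)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, length(order_idx), by = train_cfg$batch_size)) {
        bidx <- order_idx[start:min(start + train_cfg$batch_size - 1L,
                                    length(order_idx))]
        if (length(bidx) < 2L) next # batch norm needs > 1 sample
        bdata <- segments$data[, , bidx, drop = FALSE]
        if (!is.null(augment_cfg)) {
          for (j in seq_along(bidx)) {
            bdata[, , j] <- augment_segment(bdata[, , j], augment_cfg)
          }
        }
        X <- model_input(model, bdata)
        fwd <- forward_pass(model, X, training = TRUE, keep_cache = TRUE)
        model$bn <- fwd$bn
        lv <- loss_value_grad(train_cfg$loss, ages[bidx], fwd$yhat)
        grads <- backward_pass(model, fwd, lv$grad, training = TRUE)
        grads$input <- NULL
        stepped <- adam_step(model$params, grads, opt, lr)
        model$params <- stepped$params
        opt <- stepped$opt
        epoch_loss <- epoch_loss + lv$value
        n_batches <- n_batches + 1L
      }
      val_mae <- session_level_mae(model, segments, split$val)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / max(n_batches, 1L),
        val_mae = val_mae, lr = lr))
      if (val_mae < best$mae - 1e-9) {
        best <- list(mae = val_mae, params = model$params, bn = model$bn,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall %% train_cfg$scheduler_patience == 0L) {
          lr <- lr * train_cfg$scheduler_factor
        }
        if (stall >= train_cfg$early_stop_patience) break
      }
    }
  })

  clear_conv_caches(model)
  model$params <- best$params
  model$bn <- best$bn
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model$split <- split
  model$loss <- train_cfg$loss
  model
}

#' Cross-validated training and evaluation
#'
#' Runs [train_age_model()] for the requested iterations of a fold plan and
#' evaluates each iteration's best model on its held-out test fold at the
#' session level.
#'
#' @inheritParams train_age_model
#' @param iterations which iterations to run (default: all folds).
#' @return An object of class `age_cv`: per-iteration test metrics, the
#'   pooled session-level predictions, and the fitted models.
#' @export
cross_validate <- function(segments, plan,
                           iterations = seq_len(plan$n_folds),
                           model_cfg = model_preset("tiny"),
                           train_cfg = train_config(),
                           augment_cfg = augment_config()) {
  fits <- list()
  rows <- list()
  preds <- list()
  for (it in iterations) {
    fit <- train_age_model(segments, plan, it, model_cfg, train_cfg,
                           augment_cfg)
    test_pred <- predict_sessions(fit, segments[fit$split$test])
    test_pred$iteration <- it
    m <- mae(test_pred$true_age, test_pred$predicted_age)
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = it, test_mae = m,
      test_r2 = if (nrow(test_pred) >= 2 &&
                    stats::sd(test_pred$true_age) > 0) {
        r_squared(test_pred$true_age, test_pred$predicted_age)
      } else NA_real_,
      n_test_sessions = nrow(test_pred))
    preds[[length(preds) + 1L]] <- test_pred
    fits[[length(fits) + 1L]] <- fit
  }
  folds_tab <- do.call(rbind, rows)
  structure(
    list(folds = folds_tab,
         predictions = do.call(rbind, preds),
         models = fits,
         mae_ci95_upper = if (nrow(folds_tab) >= 2) {
           ci95_upper(folds_tab$test_mae)
         } else NA_real_),
    class = "age_cv"
  )
}

#' @export
print.age_cv <- function(x, ...) {
  cat(sprintf("<age_cv> %d iterations\n", nrow(x$folds)))
  cat(sprintf("  test MAE: mean %.2f years (sd %.2f)%s\n",
              mean(x$folds$test_mae), stats::sd(x$folds$test_mae),
              if (!is.na(x$mae_ci95_upper)) {
                sprintf(", CI95 upper %.2f", x$mae_ci95_upper)
              } else ""))
  if (!all(is.na(x$folds$test_r2))) {
    cat(sprintf("  test R2: mean %.2f\n", mean(x$folds$test_r2, na.rm = TRUE)))
  }
  invisible(x)
}
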