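# a model stub whose output is a fixed function of the segment: the mean of
# channel 1 (ages = signal means), letting session aggregation be tested
# without training
constant_model <- function(value) {
  m <- age_model(model_preset("tiny"), seed = 1)
  m$params$W1 <- m$params$W1 * 0
  m$params$b1 <- m$params$b1 * 0
  m$params$W2 <- m$params$W2 * 0
  m$params$W3 <- m$params$W3 * 0
  m$params$W4 <- m$params$W4 * 0
  m$params$w_head <- m$params$w_head * 0
  m$params$b_head <- value
  m
}

segments_for <- function(subject, session, state, ages, n = 4, seed = 1) {
  data <- with_toy_seed(seed, array(rnorm(8 * 500 * n), dim = c(8, 500, n)))
  eegage:::new_segments(
    data,
    data.frame(subject_id = subject, session_id = session, eye_state = state,
               age_years = ages, sex = "female",
               start_sample = seq_len(n) - 1L),
    paste0("ch", 1:8), 250)
}

test_that("session prediction is the mean of clamped segment predictions", {
  m <- constant_model(27.5)
  segs <- segments_for("s1", "s1_ses1", "EO", 30)
  sp <- predict_session(m, segs)
  expect_equal(sp$session_age, 27.5)
  expect_equal(sp$n_segments, 4)
  expect_equal(sp$segment_ages, rep(27.5, 4))
  expect_equal(sp$true_age, 30)
  # a single segment: session age equals that prediction
  sp1 <- predict_session(m, segs[1])
  expect_equal(sp1$session_age, 27.5)
  expect_error(predict_session(m, segs[integer(0)]), "no artifact-free")
})

test_that("predict_session refuses segments spanning several blocks", {
  m <- constant_model(10)
  a <- segments_for("s1", "s1_ses1", "EO", 30)
  b <- segments_for("s1", "s1_ses1", "EC", 30)
  expect_error(predict_session(m, bind_segments(a, b)), "one")
})

test_that("subject-level pooling weights sessions by segment count", {
  m <- constant_model(5)
  eo <- predict_session(m, segments_for("s1", "s1_ses1", "EO", 40, n = 2))
  ec <- predict_session(m, segments_for("s1", "s1_ses1", "EC", 40, n = 6))
  eo$segment_ages <- c(10, 20); eo$session_age <- 15
  ec$segment_ages <- c(30, 40, 30, 40, 30, 40); ec$session_age <- 35
  expect_equal(predict_subject(list(eo, ec), "both"),
               mean(c(10, 20, 30, 40, 30, 40, 30, 40)))
  expect_equal(predict_subject(list(eo, ec), "eo"), 15)
  expect_equal(predict_subject(list(eo, ec), "ec"), 35)
  expect_error(predict_subject(list(eo), "ec"), "absent")
})

test_that("pooled mean equals the segment-count-weighted mean of sessions", {
  set.seed(66)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    counts <- sample(1:8, k, replace = TRUE)
    preds <- lapply(seq_len(k), function(i) {
      structure(list(subject_id = "s", session_id = "ses", eye_state =
                       sample(c("EO", "EC"), 1),
                     segment_ages = runif(counts[i], 0, 90),
                     session_age = NA, n_segments = counts[i], true_age = 50),
                class = "session_prediction")
    })
    for (i in seq_len(k)) preds[[i]]$session_age <-
        mean(preds[[i]]$segment_ages)
    pooled <- mean(unlist(lapply(preds, `[[`, "segment_ages")))
    weighted <- sum(vapply(preds, function(p) p$session_age * p$n_segments,
                           0)) / sum(counts)
    expect_equal(pooled, weighted, tolerance = 1e-12)
  }
})

test_that("evaluation metrics agree with the metric oracles", {
  set.seed(8)
  df <- data.frame(
    subject_id = sprintf("s%d", 1:30), session_id = sprintf("s%d_ses1", 1:30),
    eye_state = "EO", n_segments = 5,
    true_age = runif(30, 5, 88), iteration = rep(1:3, each = 10))
  df$predicted_age <- pmax(df$true_age + rnorm(30, sd = 6), 0)
  ev <- evaluate_predictions(df)
  expect_equal(ev$mae, mae(df$true_age, df$predicted_age))
  expect_equal(ev$r_squared, r_squared(df$true_age, df$predicted_age))
  expect_equal(ev$pearson_r, cor(df$true_age, df$predicted_age))
  expect_equal(nrow(ev$per_fold), 3)
  expect_equal(ev$mae_ci95_upper, ci95_upper(ev$per_fold$mae))
  # perfect predictions
  df2 <- df; df2$predicted_age <- df2$true_age
  ev2 <- evaluate_predictions(df2)
  expect_equal(ev2$mae, 0)
  expect_equal(ev2$r_squared, 1)
  expect_equal(ev2$pearson_r, 1)
})

test_that("eye-state matrix fills all cells from matched predictions", {
  m <- constant_model(33)
  segs <- bind_segments(
    segments_for("s1", "s1_ses1", "EO", 30),
    segments_for("s1", "s1_ses1", "EC", 30),
    segments_for("s2", "s2_ses1", "EO", 40),
    segments_for("s2", "s2_ses1", "EC", 40))
  tab <- eye_state_matrix(list(both = m, eo = m, ec = m), segs)
  expect_identical(dim(tab), c(3L, 3L))
  # identical constant models: every cell equals mae(c(30,40), c(33,33))
  expect_true(all(abs(tab - mae(c(30, 40), c(33, 33))) < 1e-9))
})
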