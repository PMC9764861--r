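#' Cross-subject fold assignment
#'
#' Assigns whole subjects to folds (shuffle under the seed, then deal
#' round-robin), so that every eyes-open and eyes-closed segment of a
#' subject lives in exactly one fold. Across the `n_folds` cross-validation
#' iterations, each fold serves as the test set exactly once and as the
#' validation set exactly once (iteration `i` tests on fold `i` and
#' validates on fold `i %% n_folds + 1`); the remaining folds train.
#'
#' This subject-level split is what makes the reported metrics honest: a
#' segment-level split (see [make_random_split()]) lets the network memorize
#' per-subject signal idiosyncrasies and inflates validation scores.
#'
#' @param subjects character vector of subject ids (duplicates collapsed),
#'   or an `eeg_segments` object.
#' @param n_folds number of folds.
#' @param seed integer seed for the shuffle.
#' @return An object of class `fold_plan` with `assignments` (named integer
#'   vector subject -> fold) and `iterations` (data frame of test/validation
#'   fold roles).
#' @export
make_folds <- function(subjects, n_folds = 10, seed = 1L) {
  if (inherits(subjects, "eeg_segments")) {
    subjects <- subjects$meta$subject_id
  }
  subjects <- unique(as.character(subjects))
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (length(subjects) < n_folds) {
    stopf("need at least %d subjects for %d folds, got %d",
          n_folds, n_folds, length(subjects))
  }
  shuffled <- with_seed(seed, sample(subjects))
  assignments <- stats::setNames(
    rep_len(seq_len(n_folds), length(shuffled)), shuffled)
  iterations <- data.frame(
    iteration = seq_len(n_folds),
    test_fold = seq_len(n_folds),
    val_fold = seq_len(n_folds) %% n_folds + 1L
  )
  structure(
    list(n_folds = n_folds, assignments = assignments,
         iterations = iterations, type = "cross_subject", seed = seed),
    class = "fold_plan"
  )
}

#' Segment-level random split (data-leakage demonstration)
#'
#' Deals individual segments into folds ignoring subject identity, so
#' segments of one subject (often overlapping in time) land on both sides
#' of the train/validation boundary. This exists solely to demonstrate the
#' metric inflation caused by such leakage; never use it to report model
#' quality.
#'
#' @param segments an `eeg_segments` object.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return An object of class `fold_plan` with `type = "random"` and
#'   per-segment `segment_folds`.
#' @export
make_random_split <- function(segments, n_folds = 10, seed = 1L) {
  stopifnot(inherits(segments, "eeg_segments"))
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  n <- n_segments(segments)
  segment_folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  iterations <- data.frame(
    iteration = seq_len(n_folds),
    test_fold = seq_len(n_folds),
    val_fold = seq_len(n_folds) %% n_folds + 1L
  )
  structure(
    list(n_folds = n_folds, segment_folds = segment_folds,
         iterations = iterations, type = "random", seed = seed),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  what <- if (x$type == "cross_subject") {
    sprintf("%d subjects", length(x$assignments))
  } else {
    sprintf("%d segments (leakage demonstration)", length(x$segment_folds))
  }
  cat(sprintf("<fold_plan> %s split of %s into %d folds\n",
              x$type, what, x$n_folds))
  invisible(x)
}

# Resolve a plan + iteration into train/val/test segment indices.
resolve_split <- function(plan, segments, iteration) {
  stopifnot(inherits(plan, "fold_plan"), inherits(segments, "eeg_segments"))
  iteration <- check_count(iteration, "iteration")
  if (iteration > plan$n_folds) {
    stopf("iteration %d exceeds n_folds %d", iteration, plan$n_folds)
  }
  roles <- plan$iterations[iteration, ]
  seg_fold <- if (plan$type == "cross_subject") {
    f <- plan$assignments[segments$meta$subject_id]
    if (anyNA(f)) {
      stopf("segments contain subjects absent from the fold plan: %s",
            paste(unique(segments$meta$subject_id[is.na(f)]), collapse = ", "))
    }
    unname(f)
  } else {
    if (length(plan$segment_folds) != n_segments(segments)) {
      stopf("random split was built for %d segments, got %d",
            length(plan$segment_folds), n_segments(segments))
    }
    plan$segment_folds
  }
  list(
    train = which(!seg_fold %in% c(roles$test_fold, roles$val_fold)),
    val = which(seg_fold == roles$val_fold),
    test = which(seg_fold == roles$test_fold)
  )
}
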