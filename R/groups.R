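#' Assign ages to classes defined by boundary vector
#'
#' Classes are the half-open intervals `[b_i, b_{i+1})`; the last interval
#' is closed on the right so the maximum age remains classifiable.
#'
#' @param x numeric vector of ages, all within `[b_1, b_{K+1}]`.
#' @param boundaries strictly increasing numeric vector `b_1 < ... < b_{K+1}`.
#' @return Integer vector of class indices in `1..K`.
#' @export
assign_groups <- function(x, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stopf("boundaries must be strictly increasing")
  }
  K <- length(boundaries) - 1L
  if (K < 1L) stopf("need at least 2 boundaries")
  if (any(x < boundaries[1] | x > boundaries[K + 1L])) {
    stopf("ages outside [%g, %g]", boundaries[1], boundaries[K + 1L])
  }
  cls <- findInterval(x, boundaries, rightmost.closed = TRUE)
  as.integer(cls)
}

#' Balanced accuracy
#'
#' The mean over classes of the per-class recall; insensitive to class
#' imbalance (a constant predictor scores `1/K` on balanced truth).
#'
#' @param true_classes,predicted_classes integer labels in `1..K`.
#' @param K number of classes.
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(true_classes, predicted_classes,
                              K = max(true_classes)) {
  if (length(true_classes) != length(predicted_classes)) {
    stopf("label vectors differ in length")
  }
  recalls <- vapply(seq_len(K), function(k) {
    sel <- true_classes == k
    if (!any(sel)) stopf("true class %d is empty", k)
    mean(predicted_classes[sel] == k)
  }, 0)
  mean(recalls)
}

# class-balance feasibility: largest class at most twice the smallest
sizes_feasible <- function(sizes) {
  min(sizes) >= 0.5 * max(sizes)
}

#' Optimal age-group boundaries by differential evolution
#'
#' Searches for the partition of the age range into `K` groups that
#' maximizes the balanced accuracy of the class labels induced by the model
#' predictions against those induced by the true ages, subject to the
#' class-balance constraint that the largest class is at most twice the
#' smallest (computed on true-age class sizes). The outer boundaries are
#' fixed at `min(y)` and `max(y)`; the `K - 1` interior boundaries are
#' optimized with a classic rand/1/bin differential evolution, infeasible
#' candidates (unordered boundaries or balance violations) being rejected
#' with objective `-Inf`.
#'
#' @param y true ages.
#' @param y_hat predicted ages (same length).
#' @param K number of groups (>= 2).
#' @param pop_size DE population size (default `15 * (K - 1)`).
#' @param generations DE generations.
#' @param F_scale,crossover DE mutation scale and crossover probability.
#' @param seed integer seed; the search is seed-deterministic.
#' @return An object of class `age_groups`: `K`, `boundaries`, `sizes`
#'   (true-age class sizes), `balanced_accuracy`, `feasible`. If no feasible
#'   partition was found, `feasible` is `FALSE` and the accuracy is `NA`.
#' @export
optimize_boundaries <- function(y, y_hat, K, pop_size = 15L * (K - 1L),
                                generations = 200L, F_scale = 0.8,
                                crossover = 0.9, seed = 1L) {
  if (length(y) != length(y_hat)) stopf("y and y_hat differ in length")
  K <- check_count(K, "K", min = 2L)
  if (length(y) < 2L * K) stopf("need at least 2*K observations")
  lo <- min(y); hi <- max(y)
  y_hat_cl <- pmin(pmax(y_hat, lo), hi) # predictions outside the range
  objective <- function(interior) {
    b <- c(lo, interior, hi)
    if (is.unsorted(b, strictly = TRUE)) return(-Inf)
    tc <- findInterval(y, b, rightmost.closed = TRUE)
    sizes <- tabulate(tc, nbins = K)
    if (any(sizes == 0L) || !sizes_feasible(sizes)) return(-Inf)
    pc <- findInterval(y_hat_cl, b, rightmost.closed = TRUE)
    mean(vapply(seq_len(K), function(k) mean(pc[tc == k] == k), 0))
  }
  d <- K - 1L
  best <- with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * d, lo, hi), pop_size, d)
    pop <- t(apply(pop, 1, sort))
    if (d == 1L) pop <- matrix(pop, ncol = 1L)
    fit <- apply(pop, 1, objective)
    for (gen in seq_len(generations)) {
      for (i in seq_len(pop_size)) {
        others <- sample(setdiff(seq_len(pop_size), i), 3L)
        mutant <- pop[others[1], ] +
          F_scale * (pop[others[2], ] - pop[others[3], ])
        mutant <- pmin(pmax(mutant, lo), hi)
        cross <- stats::runif(d) < crossover
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        f <- objective(trial)
        if (f >= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f
        }
      }
    }
    list(x = pop[which.max(fit), ], f = max(fit))
  })
  if (!is.finite(best$f)) {
    return(structure(
      list(K = K, boundaries = NULL, sizes = NULL,
           balanced_accuracy = NA_real_, feasible = FALSE),
      class = "age_groups"))
  }
  boundaries <- c(lo, sort(best$x), hi)
  tc <- findInterval(y, boundaries, rightmost.closed = TRUE)
  structure(
    list(K = K, boundaries = boundaries, sizes = tabulate(tc, nbins = K),
         balanced_accuracy = best$f, feasible = TRUE),
    class = "age_groups"
  )
}

#' @export
print.age_groups <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<age_groups> K = %d: no feasible partition\n", x$K))
    return(invisible(x))
  }
  b <- x$boundaries
  iv <- paste0(
    "[", sprintf("%.4g", b[-length(b)]), ",", sprintf("%.4g", b[-1]),
    c(rep(")", x$K - 1L), "]"))
  cat(sprintf("<age_groups> K = %d, bAcc %.3f\n  groups: %s\n  sizes:  %s\n",
              x$K, x$balanced_accuracy, paste(iv, collapse = " "),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}
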