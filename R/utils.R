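# internal helpers shared across the package

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) stopf("'%s' must be a whole number", name)
  invisible(as.integer(x))
}

# canonical EEG frequency bands (Hz)
EEG_BANDS <- list(
  delta = c(1, 4), theta = c(4, 7), alpha = c(8, 12), beta = c(12, 30)
)

# 26-channel 10-10 montage used by the synthetic cohorts
CHANNELS_26 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4",
  "T7", "C3", "Cz", "C4", "T8", "CP3", "CPz", "CP4", "P7", "P3",
  "Pz", "P4", "P8", "O1", "Oz", "O2"
)
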