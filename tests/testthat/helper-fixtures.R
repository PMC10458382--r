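# Programmatic fixtures shared across test files.

# Deterministic batch of random windows for oracle-equivalence suites.
random_windows <- function(n, len, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- i %% 3
    if (kind == 0) rnorm(len)
    else if (kind == 1) cumsum(rnorm(len))          # drifting, colored
    else sin(seq_len(len) / 5) + 0.3 * rnorm(len)   # rhythmic + noise
  })
}

# Small two-class feature table with a clear class contrast (no signal
# processing involved): class-1 rows have larger variance-like columns.
make_separable_table <- function(n_per_class = 60, seed = 1, gap = 2) {
  set.seed(seed)
  p <- length(neoseizr:::FEATURE_NAMES)
  x0 <- matrix(rnorm(n_per_class * p), ncol = p)
  x1 <- matrix(rnorm(n_per_class * p, mean = gap), ncol = p)
  mat <- rbind(x0, x1)
  colnames(mat) <- neoseizr:::FEATURE_NAMES
  out <- as.data.frame(mat)
  out$label <- rep(c(0L, 1L), each = n_per_class)
  out <- out[sample(nrow(out)), ]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

# Standard small synthetic recording used by several files.
small_synth <- function(seed = 11, n_channels = 3, duration_s = 120,
                        segments = list(c(30, 15), c(80, 12))) {
  generate_recording(synthetic_spec(
    n_channels = n_channels, duration_s = duration_s,
    seizure_segments = segments, seed = seed))
}
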