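# Fifteen per-window features: eleven time-domain summary statistics and
# Hjorth parameters, four entropy-domain complexity measures.

FEATURE_NAMES <- c("mean", "median", "variance", "rms", "std", "skewness",
                   "kurtosis", "iqr", "hjorth_activity", "hjorth_mobility",
                   "hjorth_complexity", "permutation_entropy",
                   "shannon_entropy", "approximate_entropy", "sample_entropy")

#' Feature-extraction configuration
#'
#' Hyperparameters of the entropy features; defaults follow common EEG
#' practice (embedding order 2-3, tolerance 0.2 standard deviations,
#' 16 amplitude bins).
#'
#' @param pe_order permutation-entropy embedding order m (>= 2, default 3).
#' @param pe_delay permutation-entropy embedding delay (default 1).
#' @param apen_m approximate-entropy template length (default 2).
#' @param apen_r_coeff approximate-entropy tolerance as a multiple of the
#'   window's (population) standard deviation (default 0.2).
#' @param sampen_m sample-entropy template length (default 2).
#' @param sampen_r_coeff sample-entropy tolerance coefficient (default 0.2).
#' @param shannon_bins number of equal-width amplitude histogram bins for the
#'   Shannon entropy (default 16).
#' @param hjorth_sqrt if \code{TRUE} (default) Hjorth mobility is the square
#'   root of the derivative-to-signal variance ratio (the standard,
#'   dimensionless definition); \code{FALSE} gives the plain variance ratio.
#' @return A \code{feature_config} list.
#' @export
feature_config <- function(pe_order = 3, pe_delay = 1, apen_m = 2,
                           apen_r_coeff = 0.2, sampen_m = 2,
                           sampen_r_coeff = 0.2, shannon_bins = 16,
                           hjorth_sqrt = TRUE) {
  if (pe_order < 2) stopf("`pe_order` must be >= 2")
  if (shannon_bins < 1) stopf("`shannon_bins` must be >= 1")
  structure(list(pe_order = as.integer(pe_order),
                 pe_delay = as.integer(pe_delay),
                 apen_m = as.integer(apen_m), apen_r_coeff = apen_r_coeff,
                 sampen_m = as.integer(sampen_m),
                 sampen_r_coeff = sampen_r_coeff,
                 shannon_bins = as.integer(shannon_bins),
                 hjorth_sqrt = hjorth_sqrt),
            class = "feature_config")
}

pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

#' Basic statistical features of a window
#'
#' Mean, mid-rank median, population variance, RMS, standard deviation,
#' Pearson's second skewness coefficient \code{3 (mean - median) / sd}
#' (0 for a constant window), kurtosis
#' \code{N sum((x - mu)^4) / sum((x - mu)^2)^2}, and the interquartile range
#' with linear-interpolation quantiles.
#'
#' @param window numeric vector, length >= 4.
#' @return Named numeric vector of the eight statistics.
#' @export
basic_stats <- function(window) {
  n <- length(window)
  if (n < 4) stopf("window too short for basic statistics (length %d < 4)", n)
  mu <- mean(window)
  med <- median(window)
  v <- pop_var(window)
  s <- sqrt(v)
  dev <- window - mu
  kurt <- if (v > 0) n * sum(dev^4) / sum(dev^2)^2 else 0
  skew <- if (s > 0) 3 * (mu - med) / s else 0
  q <- quantile(window, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mu, median = med, variance = v, rms = sqrt(mean(window^2)),
    std = s, skewness = skew, kurtosis = kurt, iqr = q[2] - q[1])
}

#' Hjorth parameters
#'
#' Activity = variance of the signal; mobility = sqrt(var(diff(x))/var(x));
#' complexity = mobility(diff(x)) / mobility(x). Population variances
#' throughout, so activity equals the \code{variance} feature exactly.
#'
#' @param window numeric vector, length >= 3, non-constant.
#' @param use_sqrt see \code{hjorth_sqrt} in \code{\link{feature_config}}.
#' @return Named vector \code{c(activity, mobility, complexity)}.
#' @export
hjorth <- function(window, use_sqrt = TRUE) {
  if (length(window) < 3) stopf("window too short for Hjorth parameters")
  v0 <- pop_var(window)
  if (v0 <= 0) stopf("Hjorth parameters are undefined for a constant window")
  d1 <- diff(window)
  d2 <- diff(d1)
  v1 <- pop_var(d1)
  v2 <- pop_var(d2)
  if (use_sqrt) {
    mob <- sqrt(v1 / v0)
    mob_d <- if (v1 > 0) sqrt(v2 / v1) else 0
  } else {
    mob <- v1 / v0
    mob_d <- if (v1 > 0) v2 / v1 else 0
  }
  comp <- if (mob > 0) mob_d / mob else 0
  c(activity = v0, mobility = mob, complexity = comp)
}

# Ordinal pattern codes of the delay-embedded window; ties broken by
# position (stable order), vectorized over all embedding vectors.
ordinal_pattern_codes <- function(window, m, delay) {
  n_pat <- length(window) - (m - 1) * delay
  emb <- sapply(0:(m - 1), function(k) window[seq_len(n_pat) + k * delay])
  if (n_pat == 1) emb <- matrix(emb, nrow = 1)
  ranks <- matrix(0L, nrow = n_pat, ncol = m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      ranks[, j] <- ranks[, j] +
        (emb[, k] < emb[, j] | (emb[, k] == emb[, j] & k < j))
    }
  }
  as.vector(ranks %*% m^(seq_len(m) - 1))
}

#' Permutation entropy
#'
#' Natural-log Shannon entropy of the distribution of ordinal patterns of
#' order \code{m} (ties broken by position). Ranges from 0 (monotone signal)
#' to \code{ln(m!)} (uniform pattern distribution).
#'
#' @param window numeric vector of length >= \code{m * delay + 1}.
#' @param m embedding order (default 3).
#' @param delay embedding delay (default 1).
#' @return Non-negative entropy in nats.
#' @export
permutation_entropy <- function(window, m = 3, delay = 1) {
  if (length(window) < m * delay + 1)
    stopf("window too short for permutation entropy of order %d, delay %d", m, delay)
  codes <- ordinal_pattern_codes(window, m, delay)
  p <- tabulate(match(codes, unique(codes)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Shannon entropy of the amplitude histogram
#'
#' The window is binned into \code{bins} equal-width bins over its own
#' [min, max] range (a constant window occupies a single bin); the entropy of
#' the bin probabilities is returned in nats. Empty bins contribute nothing.
#'
#' @param window numeric vector.
#' @param bins number of bins (default 16).
#' @return Non-negative entropy in nats, at most \code{ln(bins)}.
#' @export
shannon_entropy <- function(window, bins = 16) {
  if (bins < 1) stopf("`bins` must be >= 1")
  rng <- range(window)
  if (rng[2] - rng[1] <= 0) return(0)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(window, edges, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = bins)
  p <- p[p > 0] / length(window)
  -sum(p * log(p))
}

#' Approximate entropy
#'
#' Standard ApEn with Chebyshev distance and self-matches included;
#' tolerance \code{r = r_coeff} times the window's population standard
#' deviation. A constant window returns 0.
#'
#' @param window numeric vector of length > \code{m + 1}.
#' @param m template length (default 2).
#' @param r_coeff tolerance coefficient (default 0.2).
#' @return Non-negative entropy estimate.
#' @export
approximate_entropy <- function(window, m = 2, r_coeff = 0.2) {
  if (length(window) <= m + 1)
    stopf("window too short for approximate entropy with m = %d", m)
  s <- pop_sd(window)
  if (s <= 0) return(0)
  apen_cpp(as.numeric(window), as.integer(m), r_coeff * s)
}

#' Sample entropy
#'
#' \code{-ln(A/B)} with \code{B} the count of length-\code{m} template pairs
#' within Chebyshev tolerance \code{r = r_coeff * sd} and \code{A} the count
#' for length \code{m + 1}; self-matches excluded. When no template pair
#' matches at either length the value is capped at its \code{ln(N - m)}
#' upper bound and flagged with attribute \code{capped = TRUE}.
#'
#' @inheritParams approximate_entropy
#' @return Non-negative entropy estimate (possibly with \code{capped}
#'   attribute).
#' @export
sample_entropy <- function(window, m = 2, r_coeff = 0.2) {
  n <- length(window)
  if (n <= m + 1)
    stopf("window too short for sample entropy with m = %d", m)
  s <- pop_sd(window)
  cnt <- sampen_counts_cpp(as.numeric(window), as.integer(m), r_coeff * s)
  if (cnt$B == 0 || cnt$A == 0) {
    out <- log(n - m)
    attr(out, "capped") <- TRUE
    return(out)
  }
  -log(cnt$A / cnt$B)
}

#' Compute the 15-feature vector of one window
#'
#' @param window numeric vector.
#' @param config a \code{\link{feature_config}}.
#' @return Named numeric vector of length 15 in the canonical feature order.
#' @export
feature_vector <- function(window, config = feature_config()) {
  bs <- basic_stats(window)
  hj <- if (pop_var(window) > 0) hjorth(window, config$hjorth_sqrt)
        else c(activity = 0, mobility = 0, complexity = 0)
  out <- c(bs,
           hjorth_activity = unname(hj["activity"]),
           hjorth_mobility = unname(hj["mobility"]),
           hjorth_complexity = unname(hj["complexity"]),
           permutation_entropy = permutation_entropy(window, config$pe_order,
                                                     config$pe_delay),
           shannon_entropy = shannon_entropy(window, config$shannon_bins),
           approximate_entropy = approximate_entropy(window, config$apen_m,
                                                     config$apen_r_coeff),
           sample_entropy = as.numeric(sample_entropy(window, config$sampen_m,
                                                      config$sampen_r_coeff)))
  names(out) <- FEATURE_NAMES
  out
}

#' Extract the feature table of a window set
#'
#' One row per window, labels carried through; any row with a non-finite
#' feature value is dropped with a message listing the indices.
#'
#' @param windowset a \code{window_set} from \code{\link{run_preprocess}}.
#' @param config a \code{\link{feature_config}}.
#' @return A \code{feature_table}: data frame of the 15 features plus a
#'   \code{label} column.
#' @export
extract_features <- function(windowset, config = feature_config()) {
  n <- nrow(windowset$windows)
  mat <- matrix(NA_real_, nrow = n, ncol = length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n))
    mat[i, ] <- feature_vector(windowset$windows[i, ], config)
  ok <- apply(mat, 1, function(r) all(is.finite(r)))
  if (any(!ok))
    message(sprintf("dropping %d window(s) with non-finite features: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  out <- as.data.frame(mat[ok, , drop = FALSE])
  out$label <- as.integer(windowset$labels[ok])
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write a feature table to CSV
#' @param table a \code{feature_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
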