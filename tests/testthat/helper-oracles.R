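# Independent naive reference implementations used as oracles. These are
# deliberately written from the definitions (loops, enumeration, direct
# counting) and share no code with the package internals.

oracle_basic_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  c(mean = mu, median = med, variance = v,
    rms = sqrt(sum(x^2) / n), std = s,
    skewness = if (s > 0) 3 * (mu - med) / s else 0,
    kurtosis = if (v > 0) n * sum((x - mu)^4) / (sum((x - mu)^2))^2 else 0,
    iqr = q[2] - q[1])
}

oracle_hjorth <- function(x) {
  pv <- function(z) sum((z - mean(z))^2) / length(z)
  d1 <- x[-1] - x[-length(x)]
  d2 <- d1[-1] - d1[-length(d1)]
  mob <- sqrt(pv(d1) / pv(x))
  mob_d <- sqrt(pv(d2) / pv(d1))
  c(activity = pv(x), mobility = mob, complexity = mob_d / mob)
}

# Enumerate ordinal patterns one embedding vector at a time; ties broken by
# position via the stable base order().
oracle_permutation_entropy <- function(x, m, delay) {
  n_pat <- length(x) - (m - 1) * delay
  pats <- character(n_pat)
  for (i in seq_len(n_pat)) {
    v <- x[i + (0:(m - 1)) * delay]
    pats[i] <- paste(order(v), collapse = "-")
  }
  p <- table(pats) / n_pat
  -sum(p * log(p))
}

oracle_shannon_entropy <- function(x, bins) {
  if (max(x) - min(x) <= 0) return(0)
  cuts <- seq(min(x), max(x), length.out = bins + 1)
  idx <- cut(x, cuts, include.lowest = TRUE, labels = FALSE)
  p <- as.numeric(table(idx)) / length(x)
  -sum(p * log(p))
}

# Direct-count ApEn: Chebyshev distance, self-matches included.
oracle_approximate_entropy <- function(x, m, r_coeff) {
  N <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / N)
  if (s <= 0) return(0)
  r <- r_coeff * s
  phi <- function(mm) {
    n <- N - mm + 1
    total <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / n)
    }
    total / n
  }
  phi(m) - phi(m + 1)
}

# Direct-count SampEn: self-matches excluded, templates limited to N - m.
oracle_sample_entropy <- function(x, m, r_coeff) {
  N <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / N)
  r <- r_coeff * s
  A <- 0; B <- 0
  n <- N - m
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dB <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dB <= r) {
        B <- B + 1
        dA <- max(dB, abs(x[i + m] - x[j + m]))
        if (dA <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(log(N - m))
  -log(A / B)
}

oracle_feature_vector <- function(x, cfg = feature_config()) {
  bs <- oracle_basic_stats(x)
  hj <- oracle_hjorth(x)
  c(bs, hjorth_activity = unname(hj["activity"]),
    hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    permutation_entropy = oracle_permutation_entropy(x, cfg$pe_order,
                                                     cfg$pe_delay),
    shannon_entropy = oracle_shannon_entropy(x, cfg$shannon_bins),
    approximate_entropy = oracle_approximate_entropy(x, cfg$apen_m,
                                                     cfg$apen_r_coeff),
    sample_entropy = oracle_sample_entropy(x, cfg$sampen_m,
                                           cfg$sampen_r_coeff))
}

# Pairwise-count AUC (probability a positive outscores a negative, ties 1/2).
oracle_auc <- function(scores, actual) {
  pos <- scores[actual == 1]; neg <- scores[actual == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_metrics <- function(predicted, actual) {
  tp <- sum(predicted == 1 & actual == 1)
  fp <- sum(predicted == 1 & actual == 0)
  tn <- sum(predicted == 0 & actual == 0)
  fn <- sum(predicted == 0 & actual == 1)
  n <- length(actual)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((tn + fn) / n) * ((tn + fp) / n)
  list(accuracy = po,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else 0)
}
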