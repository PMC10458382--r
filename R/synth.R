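# Synthetic neonatal EEG: pink-noise background plus rhythmic spike-wave
# bursts during declared seizure segments, with a per-second annotation track
# aligned to the segments.

#' Specification for a synthetic neonatal EEG recording
#'
#' @param n_channels number of EEG channels (default 18, a typical neonatal
#'   montage after pruning non-EEG channels).
#' @param duration_s total duration in whole seconds.
#' @param sample_rate sampling rate in Hz (default 256).
#' @param seizure_segments list of \code{c(onset_s, duration_s)} pairs; must
#'   be non-overlapping, lie within the recording, and each last more than
#'   10 s (shorter rhythmic runs do not qualify as electrographic seizures).
#' @param ictal_freq_hz fundamental frequency of the ictal spike-wave train
#'   (default 3 Hz).
#' @param ictal_amp_ratio ictal burst RMS relative to the background RMS
#'   (default 5; must exceed 1 so seizures stand out of the background).
#' @param noise_exponent spectral slope of the 1/f^a background (default 1,
#'   pink noise).
#' @param background_rms background RMS amplitude in microvolts (default 20).
#' @param n_experts number of annotation tracks to emit (default 1).
#' @param disagreement_rate per-second probability that an expert's mark is
#'   flipped relative to the ground truth (default 0, i.e. deterministic
#'   annotations).
#' @param seed RNG seed making the generated recording reproducible.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_channels = 18, duration_s = 60, sample_rate = 256,
                           seizure_segments = list(), ictal_freq_hz = 3,
                           ictal_amp_ratio = 5, noise_exponent = 1,
                           background_rms = 20, n_experts = 1,
                           disagreement_rate = 0, seed = 1) {
  if (n_channels < 1) stopf("need at least one channel")
  if (duration_s <= 0 || duration_s != round(duration_s))
    stopf("`duration_s` must be a positive whole number of seconds")
  if (ictal_amp_ratio <= 1) stopf("`ictal_amp_ratio` must exceed 1")
  segs <- lapply(seizure_segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2) stopf("each seizure segment must be c(onset_s, duration_s)")
    if (s[2] <= 10) stopf("seizure segment at %gs lasts %gs; must exceed 10 s", s[1], s[2])
    if (s[1] < 0 || s[1] + s[2] > duration_s)
      stopf("seizure segment [%g, %g) falls outside the %g s recording",
            s[1], s[1] + s[2], duration_s)
    s
  })
  if (length(segs) > 1) {
    ord <- order(vapply(segs, `[`, numeric(1), 1))
    segs <- segs[ord]
    for (i in seq_len(length(segs) - 1)) {
      if (segs[[i]][1] + segs[[i]][2] > segs[[i + 1]][1])
        stopf("seizure segments overlap at %g s", segs[[i + 1]][1])
    }
  }
  structure(list(n_channels = as.integer(n_channels),
                 duration_s = as.integer(duration_s),
                 sample_rate = as.numeric(sample_rate),
                 seizure_segments = segs,
                 ictal_freq_hz = as.numeric(ictal_freq_hz),
                 ictal_amp_ratio = as.numeric(ictal_amp_ratio),
                 noise_exponent = as.numeric(noise_exponent),
                 background_rms = as.numeric(background_rms),
                 n_experts = as.integer(n_experts),
                 disagreement_rate = as.numeric(disagreement_rate),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 1/f^a noise by frequency-domain shaping of seeded white Gaussian noise;
# returned with unit RMS.
pink_noise <- function(n, exponent = 1) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1e-6, seq_len(n - 1))                 # suppress DC, keep symmetry
  f <- pmin(f, n - f)                          # two-sided frequency index
  f[1] <- Inf                                  # zero out DC entirely
  shaped <- spec * f^(-exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Rhythmic spike-wave burst: fundamental plus sharpened harmonics, unit RMS.
spike_wave <- function(t, freq, phase = 0) {
  w <- 0.8 * sin(2 * pi * freq * t + phase) +
       0.45 * sin(4 * pi * freq * t + 2 * phase) +
       0.25 * sin(6 * pi * freq * t + 3 * phase)
  w / sqrt(mean(w^2))
}

#' Generate a synthetic recording with aligned annotations
#'
#' Background activity is seeded pink noise per channel. Within each seizure
#' segment a rhythmic spike-wave train at \code{ictal_freq_hz} is added to
#' every channel, scaled so its RMS is \code{ictal_amp_ratio} times the
#' channel's background RMS (with a half-second raised-cosine taper at the
#' segment edges). The annotation marks second \code{s} iff it lies inside a
#' seizure segment. Output is a pure function of the spec (seed included).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list with elements \code{recording}
#'   (\code{\link{eeg_recording}}) and \code{annotation}
#'   (\code{\link{annotation_track}}, \code{n_experts} rows).
#' @examples
#' out <- generate_recording(synthetic_spec(
#'   n_channels = 2, duration_s = 60, seizure_segments = list(c(20, 15))))
#' sum(out$annotation$marks)  # 15 seizure-marked seconds
#' @export
generate_recording <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stopf("`spec` must be a synthetic_spec")
  local_seed(spec$seed, {
    n_t <- spec$duration_s * spec$sample_rate
    if (n_t != round(n_t)) stopf("duration x sample rate must be an integer sample count")
    n_t <- as.integer(n_t)
    t_axis <- (seq_len(n_t) - 1) / spec$sample_rate
    samples <- matrix(0, nrow = spec$n_channels, ncol = n_t)
    for (ch in seq_len(spec$n_channels)) {
      bg <- spec$background_rms * pink_noise(n_t, spec$noise_exponent)
      x <- bg
      for (seg in spec$seizure_segments) {
        idx <- which(t_axis >= seg[1] & t_axis < seg[1] + seg[2])
        phase <- runif(1, 0, 2 * pi)
        burst <- spike_wave(t_axis[idx], spec$ictal_freq_hz, phase)
        taper_n <- min(length(idx) %/% 2, round(0.5 * spec$sample_rate))
        if (taper_n > 0) {
          ramp <- 0.5 * (1 - cos(pi * seq_len(taper_n) / taper_n))
          env <- rep(1, length(idx))
          env[seq_len(taper_n)] <- ramp
          env[length(idx) - taper_n + seq_len(taper_n)] <- rev(ramp)
          burst <- burst * env
        }
        x[idx] <- x[idx] + spec$ictal_amp_ratio * spec$background_rms * burst
      }
      samples[ch, ] <- x
    }
    secs <- seq_len(spec$duration_s) - 1
    truth <- rep(0L, spec$duration_s)
    for (seg in spec$seizure_segments)
      truth[secs >= seg[1] & secs < seg[1] + seg[2]] <- 1L
    marks <- matrix(rep(truth, each = spec$n_experts), nrow = spec$n_experts)
    if (spec$disagreement_rate > 0) {
      flips <- matrix(runif(length(marks)) < spec$disagreement_rate,
                      nrow = spec$n_experts)
      marks <- abs(marks - flips * 1L)
    }
    labels <- sprintf("EEG%02d", seq_len(spec$n_channels))
    list(recording = eeg_recording(samples, spec$sample_rate, labels),
         annotation = annotation_track(marks, subject_id = "synthetic"))
  })
}
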