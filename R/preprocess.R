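# Preprocessing chain: channel pruning -> downsampling -> high-pass ->
# min-max scaling -> fixed-length windowing -> threshold-based labeling.

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding
# and steady-state initialization (previous inputs pinned to the first
# sample, previous outputs to its DC response), so a constant signal passes
# with no step transient and a high-pass removes DC essentially exactly.
zerophase_filter <- function(bf, x) {
  b <- bf$b; a <- bf$a
  p <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= p + 1)
    stopf("signal too short to filter (length %d, need > %d)", n, p + 1)
  dc_gain <- sum(b) / sum(a)
  run <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1),
                              init.y = rep(z[1] * dc_gain, length(a) - 1)))
  }
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(p + 1):(p + n)]
}

#' Preprocessing configuration
#'
#' @param keep_channels character vector of channel labels to keep, or
#'   \code{"all"}.
#' @param target_rate sampling rate after downsampling, Hz (default 32; must
#'   divide the source rate).
#' @param hp_cutoff high-pass cutoff frequency, Hz (default 0.5).
#' @param hp_order high-pass Butterworth order (default 5, applied
#'   forward-backward so the effective attenuation is doubled).
#' @param window_s window length in seconds (default 8).
#' @param vt_threshold seizure-second count a window must strictly exceed to
#'   be labeled seizure (default 4, half a window).
#' @param consensus_rule how multi-expert annotations are collapsed before
#'   labeling: \code{"any"}, \code{"majority"} or \code{"all"}.
#' @param filter_before_downsample if \code{TRUE}, apply the high-pass at the
#'   source rate before downsampling instead of after.
#' @param constant_channel_zero if \code{TRUE}, min-max scaling maps a
#'   constant channel to all zeros instead of raising an error.
#' @return A \code{preprocess_config} list.
#' @export
preprocess_config <- function(keep_channels = "all", target_rate = 32,
                              hp_cutoff = 0.5, hp_order = 5, window_s = 8,
                              vt_threshold = 4,
                              consensus_rule = c("any", "majority", "all"),
                              filter_before_downsample = FALSE,
                              constant_channel_zero = FALSE) {
  consensus_rule <- match.arg(consensus_rule)
  if (hp_cutoff <= 0 || hp_cutoff >= target_rate / 2)
    stopf("`hp_cutoff` must lie in (0, target_rate/2)")
  if (vt_threshold < 0 || vt_threshold > window_s)
    stopf("`vt_threshold` must lie in [0, window_s]")
  structure(list(keep_channels = keep_channels, target_rate = target_rate,
                 hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order),
                 window_s = window_s, vt_threshold = vt_threshold,
                 consensus_rule = consensus_rule,
                 filter_before_downsample = filter_before_downsample,
                 constant_channel_zero = constant_channel_zero),
            class = "preprocess_config")
}

#' Keep a subset of channels, in the requested order
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param keep character vector of labels to keep (output order follows
#'   \code{keep}), or \code{"all"}.
#' @return An \code{eeg_recording} with only the requested channels.
#' @export
select_channels <- function(recording, keep) {
  if (identical(keep, "all")) return(recording)
  missing <- setdiff(keep, recording$channel_labels)
  if (length(missing))
    stopf("unknown channel label(s): %s", paste(missing, collapse = ", "))
  idx <- match(keep, recording$channel_labels)
  eeg_recording(recording$samples[idx, , drop = FALSE], recording$sample_rate,
                channel_labels = keep, start_time = recording$start_time)
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (order-8 Butterworth at 0.8 times
#' the target Nyquist, forward-backward) and keeps every q-th sample, where
#' q = source rate / target rate must be an integer.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param target_rate target sampling rate in Hz.
#' @return The downsampled \code{eeg_recording}.
#' @export
downsample <- function(recording, target_rate) {
  fs <- recording$sample_rate
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9)
    stopf("downsampling factor %g Hz -> %g Hz is not an integer (%.4g)",
          fs, target_rate, q)
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  bf <- signal::butter(8, 0.8 / q, type = "low")
  n_out <- floor(ncol(recording$samples) / q)
  idx <- seq(1L, by = q, length.out = n_out)
  out <- t(apply(recording$samples, 1, function(x)
    zerophase_filter(bf, x)[idx]))
  if (n_channels(recording) == 1) out <- matrix(out, nrow = 1)
  eeg_recording(out, target_rate, channel_labels = recording$channel_labels,
                start_time = recording$start_time)
}

#' Zero-phase high-pass filter
#'
#' Order-\code{order} Butterworth high-pass applied forward-backward
#' (zero phase) to every channel; removes DC and slow drift.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order (default 5).
#' @return The filtered \code{eeg_recording}.
#' @export
highpass <- function(recording, cutoff, order = 5) {
  nyq <- recording$sample_rate / 2
  if (cutoff >= nyq)
    stopf("high-pass cutoff %g Hz is not below Nyquist (%g Hz)", cutoff, nyq)
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  out <- t(apply(recording$samples, 1, function(x) zerophase_filter(bf, x)))
  if (n_channels(recording) == 1) out <- matrix(out, nrow = 1)
  eeg_recording(out, recording$sample_rate,
                channel_labels = recording$channel_labels,
                start_time = recording$start_time)
}

#' Min-max scale every channel to [0, 1]
#'
#' Per channel over the whole recording: \code{(x - min) / (max - min)}.
#' Scaling per recording (not per window) preserves amplitude contrast
#' between ictal and background windows.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param constant_channel_zero map a constant channel to all zeros instead
#'   of raising an error.
#' @return The scaled \code{eeg_recording}; each non-constant channel attains
#'   both 0 and 1.
#' @export
minmax_scale <- function(recording, constant_channel_zero = FALSE) {
  out <- recording$samples
  for (ch in seq_len(nrow(out))) {
    rng <- range(out[ch, ])
    if (rng[2] - rng[1] <= 0) {
      if (!constant_channel_zero)
        stopf("channel \"%s\" is constant; min-max scaling is degenerate",
              recording$channel_labels[ch])
      out[ch, ] <- 0
    } else {
      out[ch, ] <- (out[ch, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  eeg_recording(out, recording$sample_rate,
                channel_labels = recording$channel_labels,
                start_time = recording$start_time)
}

#' Cut a recording into fixed-length one-dimensional channel windows
#'
#' Non-overlapping (by default) contiguous windows per channel; a trailing
#' partial window is dropped. Rows are ordered channel-major: all windows of
#' channel 1 in time order, then channel 2, and so on.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param window_s window length in seconds.
#' @param stride_s hop between window starts in seconds (default
#'   \code{window_s}, i.e. non-overlapping).
#' @return List with \code{windows} (n x L matrix), \code{channel_index},
#'   \code{window_start_s}.
#' @export
segment_windows <- function(recording, window_s, stride_s = window_s) {
  fs <- recording$sample_rate
  L <- as.integer(round(window_s * fs))
  hop <- as.integer(round(stride_s * fs))
  n_t <- ncol(recording$samples)
  if (n_t < L)
    stopf("recording (%.3g s) is shorter than one %g s window",
          duration_seconds(recording), window_s)
  starts <- seq(1L, n_t - L + 1L, by = hop)
  n_ch <- n_channels(recording)
  windows <- matrix(0, nrow = n_ch * length(starts), ncol = L)
  channel_index <- integer(nrow(windows))
  window_start_s <- numeric(nrow(windows))
  row <- 0L
  for (ch in seq_len(n_ch)) {
    for (s in starts) {
      row <- row + 1L
      windows[row, ] <- recording$samples[ch, s:(s + L - 1L)]
      channel_index[row] <- ch
      window_start_s[row] <- (s - 1L) / fs
    }
  }
  list(windows = windows, channel_index = channel_index,
       window_start_s = window_start_s)
}

#' Label time-windows from per-second annotations
#'
#' Collapses multi-expert marks with \code{\link{merge_expert_tracks}}, then
#' labels time-window \code{w} (seconds \code{[w*window_s, (w+1)*window_s)})
#' as seizure iff the count of seizure-marked seconds in it strictly exceeds
#' \code{vt}.
#'
#' @param track an \code{\link{annotation_track}}.
#' @param n_windows number of time-windows to label.
#' @param window_s window length in whole seconds.
#' @param vt threshold in seconds; a window needs more than \code{vt}
#'   seizure seconds to be labeled 1.
#' @param rule consensus rule passed to \code{merge_expert_tracks}.
#' @return Integer 0/1 vector of length \code{n_windows}.
#' @export
label_windows <- function(track, n_windows, window_s, vt,
                          rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  consensus <- merge_expert_tracks(track, rule)$marks[1, ]
  need <- n_windows * window_s
  if (length(consensus) < need)
    stopf("annotation covers %d s but %d windows of %g s need %d s",
          length(consensus), n_windows, window_s, need)
  vapply(seq_len(n_windows), function(w) {
    secs <- consensus[((w - 1L) * window_s + 1L):(w * window_s)]
    as.integer(sum(secs) > vt)
  }, integer(1))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: channel selection, downsampling, zero-phase high-pass,
#' min-max scaling, windowing, and threshold labeling (labels broadcast to
#' all channels of a time slot).
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param track aligned \code{\link{annotation_track}}.
#' @param config a \code{\link{preprocess_config}}.
#' @return A \code{window_set}: list with \code{windows} (n x L matrix),
#'   \code{labels}, \code{channel_index}, \code{window_start_s},
#'   \code{sample_rate}, \code{window_s}.
#' @export
run_preprocess <- function(recording, track, config = preprocess_config()) {
  rec <- select_channels(recording, config$keep_channels)
  if (config$filter_before_downsample) {
    rec <- highpass(rec, config$hp_cutoff, config$hp_order)
    rec <- downsample(rec, config$target_rate)
  } else {
    rec <- downsample(rec, config$target_rate)
    rec <- highpass(rec, config$hp_cutoff, config$hp_order)
  }
  rec <- minmax_scale(rec, config$constant_channel_zero)
  seg <- segment_windows(rec, config$window_s)
  n_time_windows <- length(unique(seg$window_start_s))
  time_labels <- label_windows(track, n_time_windows, config$window_s,
                               config$vt_threshold, config$consensus_rule)
  slot <- match(seg$window_start_s, sort(unique(seg$window_start_s)))
  structure(list(windows = seg$windows, labels = time_labels[slot],
                 channel_index = seg$channel_index,
                 window_start_s = seg$window_start_s,
                 sample_rate = rec$sample_rate, window_s = config$window_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples (%g s @ %g Hz), %d seizure-labeled\n",
              nrow(x$windows), ncol(x$windows), x$window_s, x$sample_rate,
              sum(x$labels)))
  invisible(x)
}
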