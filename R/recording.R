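#' Multi-channel EEG recording
#'
#' Container for a multi-channel EEG signal: a channels-by-timepoints numeric
#' matrix, a common sampling rate in Hz, and channel labels. All channels must
#' share one length and one sampling rate.
#'
#' @param samples numeric matrix, channels in rows, timepoints in columns
#'   (microvolt scale by convention).
#' @param sample_rate sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   \code{"Ch1"}, \code{"Ch2"}, ...
#' @param start_time optional \code{POSIXct} acquisition start.
#'
#' @return An object of class \code{eeg_recording} with elements
#'   \code{samples}, \code{sample_rate}, \code{channel_labels},
#'   \code{start_time}.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), nrow = 2), 256)
#' duration_seconds(rec)
#' @export
eeg_recording <- function(samples, sample_rate, channel_labels = NULL,
                          start_time = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric matrix (channels x timepoints)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stopf("`sample_rate` must be a positive scalar (Hz)")
  n_ch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(n_ch))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n_ch)
    stopf("got %d channel labels for %d channels", length(channel_labels), n_ch)
  if (anyDuplicated(channel_labels))
    stopf("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         channel_labels = channel_labels, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s), %d timepoints @ %g Hz (%.1f s)\n",
              n_channels(x), ncol(x$samples), x$sample_rate,
              duration_seconds(x)))
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an \code{eeg_recording}.
#' @return timepoints / sample_rate, in seconds.
#' @export
duration_seconds <- function(recording) {
  ncol(recording$samples) / recording$sample_rate
}

#' Number of channels in a recording
#' @param recording an \code{eeg_recording}.
#' @return integer channel count.
#' @export
n_channels <- function(recording) nrow(recording$samples)

#' Per-second expert seizure annotations
#'
#' One or more experts' binary per-second seizure marks for a single subject:
#' an experts-by-seconds 0/1 matrix.
#'
#' @param marks 0/1 matrix (experts in rows, seconds in columns) or a 0/1
#'   vector for a single expert.
#' @param subject_id subject identifier (character scalar).
#' @return An object of class \code{annotation_track}.
#' @examples
#' annotation_track(c(0, 1, 1, 0), "7")
#' @export
annotation_track <- function(marks, subject_id = "unknown") {
  if (is.vector(marks)) marks <- matrix(marks, nrow = 1)
  if (!is.matrix(marks)) stopf("`marks` must be a matrix or vector")
  storage.mode(marks) <- "integer"
  if (length(marks) && !all(marks %in% c(0L, 1L)))
    stopf("annotation marks must all be 0 or 1")
  structure(list(marks = marks, subject_id = as.character(subject_id)),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> subject %s: %d expert(s) x %d s, %d seizure-second(s)\n",
              x$subject_id, nrow(x$marks), ncol(x$marks), sum(x$marks)))
  invisible(x)
}

#' Annotated seconds in a track
#' @param track an \code{annotation_track}.
#' @return number of annotated seconds (columns).
#' @export
n_seconds <- function(track) ncol(track$marks)
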