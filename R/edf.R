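# EDF (European Data Format) container I/O.
#
# EDF stores a 256-byte fixed header, 256 bytes of per-signal header fields,
# then data records of little-endian 16-bit integers (one block per signal per
# record). Physical values are recovered by the linear map defined by the
# physical/digital min/max header fields, so a write/read round trip is exact
# up to the 16-bit quantization step (physical range / 65535).

EDF_DIGITAL_MIN <- -32768L
EDF_DIGITAL_MAX <- 32767L

edf_field <- function(x, width) {
  s <- substr(as.character(x)[1], 1L, width)
  formatC(s, width = width, flag = "-")
}

# 8-char ASCII numeric field for a physical bound. Rounded outward (dirn -1
# for a minimum, +1 for a maximum) so the encoded range always contains the
# data and no sample clips.
edf_num_field <- function(x, dirn) {
  for (digits in 7:2) {
    s <- formatC(x, format = "g", digits = digits, width = -1)
    if (nchar(s) > 8) next
    v <- as.numeric(s)
    if ((dirn < 0 && v <= x) || (dirn > 0 && v >= x))
      return(formatC(s, width = 8, flag = "-"))
    delta <- abs(v) * 10^(-digits + 1) + 1e-300
    s2 <- formatC(v + dirn * delta, format = "g", digits = digits, width = -1)
    v2 <- as.numeric(s2)
    if (nchar(s2) <= 8 && ((dirn < 0 && v2 <= x) || (dirn > 0 && v2 >= x)))
      return(formatC(s2, width = 8, flag = "-"))
  }
  stopf("cannot encode physical bound %g in an 8-character EDF field", x)
}

#' Write a recording to an EDF file
#'
#' Encodes each channel as one EDF signal using the full 16-bit digital range
#' scaled to the channel's physical min/max. Record duration is one second, so
#' the sampling rate must be a positive integer and the recording a whole
#' number of seconds.
#'
#' @param recording an \code{\link{eeg_recording}}.
#' @param path output file path.
#' @param physical_dim physical dimension string stored per signal
#'   (default \code{"uV"}).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path, physical_dim = "uV") {
  if (!inherits(recording, "eeg_recording"))
    stopf("`recording` must be an eeg_recording")
  n_ch <- n_channels(recording)
  if (n_ch == 0) stopf("cannot write an EDF file with 0 channels")
  fs <- recording$sample_rate
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate, got %g", fs)
  n_t <- ncol(recording$samples)
  if (n_t == 0) stopf("cannot write an EDF file with 0 timepoints")
  if (n_t %% fs != 0)
    stopf("recording length (%d samples) is not a whole number of seconds at %g Hz",
          n_t, fs)
  n_rec <- n_t %/% fs

  pmin <- apply(recording$samples, 1, min)
  pmax <- apply(recording$samples, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1  # avoid a degenerate scaling for constant channels
  # header fields are ASCII with limited precision; reuse the printed values
  # for scaling so the round trip matches the file contents, not the originals
  pmin_s <- vapply(pmin, edf_num_field, character(1), dirn = -1)
  pmax_s <- vapply(pmax, edf_num_field, character(1), dirn = 1)
  pmin_h <- as.numeric(trimws(pmin_s))
  pmax_h <- as.numeric(trimws(pmax_s))
  pmin_h[pmax_h - pmin_h <= 0] <- pmax_h[pmax_h - pmin_h <= 0] - 1

  st <- recording$start_time
  date_s <- if (inherits(st, "POSIXt")) format(st, "%d.%m.%y") else "01.01.00"
  time_s <- if (inherits(st, "POSIXt")) format(st, "%H.%M.%S") else "00.00.00"
  header_bytes <- 256L + 256L * n_ch

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  put(edf_field("0", 8))
  put(edf_field("X X X X", 80))
  put(edf_field(paste("Startdate X X X", "neoseizr"), 80))
  put(edf_field(date_s, 8))
  put(edf_field(time_s, 8))
  put(edf_field(header_bytes, 8))
  put(edf_field("", 44))
  put(edf_field(n_rec, 8))
  put(edf_field("1", 8))
  put(edf_field(n_ch, 4))
  for (lab in recording$channel_labels) put(edf_field(lab, 16))
  for (i in seq_len(n_ch)) put(edf_field("", 80))
  for (i in seq_len(n_ch)) put(edf_field(physical_dim, 8))
  for (i in seq_len(n_ch)) put(pmin_s[i])
  for (i in seq_len(n_ch)) put(pmax_s[i])
  for (i in seq_len(n_ch)) put(edf_field(EDF_DIGITAL_MIN, 8))
  for (i in seq_len(n_ch)) put(edf_field(EDF_DIGITAL_MAX, 8))
  for (i in seq_len(n_ch)) put(edf_field("", 80))
  for (i in seq_len(n_ch)) put(edf_field(fs, 8))
  for (i in seq_len(n_ch)) put(edf_field("", 32))

  drange <- EDF_DIGITAL_MAX - EDF_DIGITAL_MIN
  scale <- (pmax_h - pmin_h) / drange
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(n_ch)) {
      d <- round((recording$samples[ch, idx] - pmin_h[ch]) / scale[ch]) +
        EDF_DIGITAL_MIN
      d <- pmin(pmax(d, EDF_DIGITAL_MIN), EDF_DIGITAL_MAX)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads every signal of an EDF file, converting digital values back to
#' physical units. All signals must share one sampling rate; heterogeneous
#' rates are rejected with the offending channels named.
#'
#' @param path path to an existing EDF file.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  take <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stopf("malformed EDF header: truncated file %s", path)
    trimws(rawToChar(raw))
  }
  take(8)                       # version
  take(80); take(80)            # patient / recording id
  take(8); take(8)              # date / time
  header_bytes <- suppressWarnings(as.integer(take(8)))
  take(44)
  n_rec <- suppressWarnings(as.integer(take(8)))
  rec_dur <- suppressWarnings(as.numeric(take(8)))
  n_sig <- suppressWarnings(as.integer(take(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, n_sig)) || n_sig < 1 || n_rec < 0)
    stopf("malformed EDF header in %s", path)

  labels <- vapply(seq_len(n_sig), function(i) take(16), character(1))
  for (i in seq_len(n_sig)) take(80)       # transducer
  for (i in seq_len(n_sig)) take(8)        # physical dimension
  pmin <- vapply(seq_len(n_sig), function(i) as.numeric(take(8)), numeric(1))
  pmax <- vapply(seq_len(n_sig), function(i) as.numeric(take(8)), numeric(1))
  dmin <- vapply(seq_len(n_sig), function(i) as.numeric(take(8)), numeric(1))
  dmax <- vapply(seq_len(n_sig), function(i) as.numeric(take(8)), numeric(1))
  for (i in seq_len(n_sig)) take(80)       # prefiltering
  spr <- vapply(seq_len(n_sig), function(i) as.integer(take(8)), integer(1))
  for (i in seq_len(n_sig)) take(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stopf("malformed EDF signal header in %s", path)

  rates <- spr / rec_dur
  if (length(unique(rates)) > 1L)
    stopf("heterogeneous sampling rates in %s: %s", path,
          paste(sprintf("%s=%g Hz", labels, rates), collapse = ", "))

  n_per_rec <- sum(spr)
  samples <- matrix(0, nrow = n_sig, ncol = n_rec * spr[1])
  offsets <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = n_per_rec, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < n_per_rec)
      stopf("truncated EDF data record %d in %s", r, path)
    for (ch in seq_len(n_sig)) {
      d <- block[(offsets[ch] + 1L):offsets[ch + 1L]]
      idx <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      samples[ch, idx] <- (d - dmin[ch]) * (pmax[ch] - pmin[ch]) /
        (dmax[ch] - dmin[ch]) + pmin[ch]
    }
  }
  eeg_recording(samples, rates[1], channel_labels = make.unique(labels))
}
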