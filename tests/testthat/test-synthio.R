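test_that("EDF write/read round trip preserves shape, rate, labels and values", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(2 * 2560, sd = 40), nrow = 2), 256,
                       channel_labels = c("Fp1", "Fp2"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_identical(dim(back$samples), c(2L, 2560L))
  expect_equal(back$sample_rate, 256)
  expect_identical(back$channel_labels, c("Fp1", "Fp2"))
  # quantization step = physical range / 16-bit digital range
  step <- (max(rec$samples) - min(rec$samples)) / 65535
  expect_lt(max(abs(back$samples - rec$samples)), step)
})

test_that("EDF round trip of a constant channel stays within quantization", {
  rec <- eeg_recording(matrix(7.5, nrow = 1, ncol = 256), 256)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  # constant channel gets a widened 1-unit physical range
  expect_lt(max(abs(back$samples - 7.5)), 1 / 65535 + 1e-9)
})

test_that("degenerate recordings are rejected by the EDF writer", {
  expect_error(write_edf(eeg_recording(matrix(0, 0, 10), 256), tempfile()),
               "0 channels")
  rec <- eeg_recording(matrix(rnorm(300), nrow = 1), 256)
  expect_error(write_edf(rec, tempfile()), "whole number of seconds")
})

test_that("heterogeneous sampling rates are rejected with channels named", {
  # hand-build a 2-signal EDF whose second signal has twice the rate
  f <- withr::local_tempfile(fileext = ".edf")
  con <- file(f, "wb")
  put <- function(s, w) writeChar(formatC(substr(s, 1, w), width = w,
                                          flag = "-"), con,
                                  nchars = w, eos = NULL)
  put("0", 8); put("p", 80); put("r", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 + 256 * 2), 8); put("", 44)
  put("1", 8); put("1", 8); put("2", 4)
  put("SlowCh", 16); put("FastCh", 16)
  put("", 80); put("", 80); put("uV", 8); put("uV", 8)
  put("-100", 8); put("-100", 8); put("100", 8); put("100", 8)
  put("-32768", 8); put("-32768", 8); put("32767", 8); put("32767", 8)
  put("", 80); put("", 80)
  put("256", 8); put("512", 8)
  put("", 32); put("", 32)
  writeBin(integer(256 + 512), con, size = 2L, endian = "little")
  close(con)
  expect_error(read_edf(f), "heterogeneous sampling rates.*SlowCh.*FastCh")
})

test_that("missing or truncated EDF files raise explicit errors", {
  expect_error(read_edf(tempfile(fileext = ".edf")), "not found")
  f <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(rep(48, 100)), f)
  expect_error(read_edf(f), "malformed|truncated")
})

test_that("an independent EDF reader (python-mne) agrees with write_edf output", {
  rec <- generate_recording(synthetic_spec(n_channels = 18, duration_s = 12,
                                           seed = 3))$recording
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  out_csv <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(r'%s', preload=True, verbose='ERROR')\n",
    "d = raw.get_data() * 1e6\n",  # mne converts uV to V on read
    "np.savetxt(r'%s', np.c_[[d.shape[0]], [d.shape[1]],",
    " [raw.info['sfreq']], [d[4, 100]], [d[17, 2000]]], delimiter=',')\n"),
    f, out_csv)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  system2(py, sf, stdout = TRUE, stderr = TRUE)
  vals <- scan(out_csv, sep = ",", quiet = TRUE)
  expect_equal(vals[1], 18)
  expect_equal(vals[2], 12 * 256)
  expect_equal(vals[3], 256)
  step <- (max(rec$samples) - min(rec$samples)) / 65535
  expect_lt(abs(vals[4] - rec$samples[5, 101]), 2 * step)
  expect_lt(abs(vals[5] - rec$samples[18, 2001]), 2 * step)
})

test_that("annotation CSV read extracts the right subject and validates cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5,7,9", "0,0,1", "0,1,1", "1,1,0", "0,0,0"), f)
  tr <- read_annotation_csv(f, "7")
  expect_s3_class(tr, "annotation_track")
  expect_identical(tr$marks, matrix(c(0L, 1L, 1L, 0L), nrow = 1))
  expect_identical(tr$subject_id, "7")
  expect_error(read_annotation_csv(f, "99"), "not found")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5", "0", "2", "1"), f2)
  expect_error(read_annotation_csv(f2, "5"), "row 2")
})

test_that("annotation CSV round trip preserves marks; trailing blanks drop", {
  tr <- annotation_track(c(0L, 1L, 1L, 0L, 1L), "23")
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(tr, f)
  back <- read_annotation_csv(f, "23")
  expect_identical(back$marks, tr$marks)
  # shorter subject alongside a longer one: blanks after its end are dropped
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,0", "0,1", ",1"), f3)
  expect_identical(ncol(read_annotation_csv(f3, "a")$marks), 2L)
  expect_identical(ncol(read_annotation_csv(f3, "b")$marks), 3L)
})

test_that("consensus rules count votes correctly and imply each other", {
  tracks <- list(annotation_track(c(1L, 0L)), annotation_track(c(1L, 1L)),
                 annotation_track(c(0L, 0L)))
  expect_identical(merge_expert_tracks(tracks, "majority")$marks[1, ], c(1L, 0L))
  expect_identical(merge_expert_tracks(tracks, "any")$marks[1, ], c(1L, 1L))
  expect_identical(merge_expert_tracks(tracks, "all")$marks[1, ], c(0L, 0L))
  expect_error(merge_expert_tracks(list(annotation_track(c(1L, 0L)),
                                        annotation_track(c(1L, 0L, 1L)))),
               "differing lengths")
  # pointwise implication all => majority => any over random expert panels
  set.seed(9)
  for (i in 1:25) {
    tr <- annotation_track(matrix(rbinom(3 * 40, 1, 0.3), nrow = 3))
    a <- merge_expert_tracks(tr, "all")$marks[1, ]
    m <- merge_expert_tracks(tr, "majority")$marks[1, ]
    y <- merge_expert_tracks(tr, "any")$marks[1, ]
    expect_true(all(a <= m))
    expect_true(all(m <= y))
  }
})

test_that("generated recordings honor the spec and are seed-deterministic", {
  spec <- synthetic_spec(n_channels = 2, duration_s = 60,
                         seizure_segments = list(c(20, 15)), seed = 7)
  out <- generate_recording(spec)
  expect_identical(sum(out$annotation$marks), 15L)
  expect_identical(dim(out$recording$samples), c(2L, 60L * 256L))
  out2 <- generate_recording(spec)
  expect_identical(out$recording$samples, out2$recording$samples)
  expect_identical(out$annotation$marks, out2$annotation$marks)
  # annotation seconds never exceed recording duration
  expect_lte(n_seconds(out$annotation) * spec$sample_rate,
             ncol(out$recording$samples))
})

test_that("ictal windows carry roughly the requested amplitude ratio", {
  spec <- synthetic_spec(n_channels = 4, duration_s = 90,
                         seizure_segments = list(c(30, 20)),
                         ictal_amp_ratio = 5, seed = 21)
  out <- generate_recording(spec)
  fs <- spec$sample_rate
  t_axis <- (seq_len(ncol(out$recording$samples)) - 1) / fs
  ictal <- t_axis >= 33 & t_axis < 47      # interior, clear of the taper
  backg <- t_axis < 28 | t_axis >= 52
  for (ch in 1:4) {
    ratio <- sqrt(mean(out$recording$samples[ch, ictal]^2)) /
      sqrt(mean(out$recording$samples[ch, backg]^2))
    expect_gt(ratio, 5 * 0.7)
    expect_lt(ratio, 5 * 1.3)
  }
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(seizure_segments = list(c(5, 8))), "exceed 10 s")
  expect_error(synthetic_spec(duration_s = 30,
                              seizure_segments = list(c(25, 12))),
               "outside")
  expect_error(synthetic_spec(duration_s = 100,
                              seizure_segments = list(c(10, 15), c(20, 15))),
               "overlap")
})
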