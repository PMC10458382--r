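# Per-second annotation CSVs: header row of subject IDs, one row per second,
# cells in {0,1} (one file per expert in the multi-expert layout).

#' Read one subject's per-second annotations from a CSV file
#'
#' The file layout is one column per subject (header row of subject IDs) and
#' one row per second of recording. Trailing blank cells are dropped so
#' subjects of different durations can share a file.
#'
#' @param path path to the annotation CSV.
#' @param subject_id column (subject) to extract, as a character scalar.
#' @return A single-expert \code{\link{annotation_track}}.
#' @export
read_annotation_csv <- function(path, subject_id) {
  if (!file.exists(path)) stopf("annotation CSV not found: %s", path)
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  subject_id <- as.character(subject_id)
  if (!subject_id %in% names(tab))
    stopf("subject \"%s\" not found in %s (subjects: %s)", subject_id, path,
          paste(names(tab), collapse = ", "))
  cells <- trimws(tab[[subject_id]])
  keep <- cells != "" & !is.na(cells)
  # trailing blanks only: a blank before the last non-blank second is corrupt
  last <- if (any(keep)) max(which(keep)) else 0L
  if (last > 0 && any(!keep[seq_len(last)]))
    stopf("blank annotation cell at row %d of subject \"%s\" in %s",
          which(!keep[seq_len(last)])[1], subject_id, path)
  cells <- cells[seq_len(last)]
  bad <- which(!cells %in% c("0", "1"))
  if (length(bad))
    stopf("non-binary annotation value \"%s\" at row %d of subject \"%s\" in %s",
          cells[bad[1]], bad[1], subject_id, path)
  annotation_track(as.integer(cells), subject_id = subject_id)
}

#' Write annotation tracks to a CSV file
#'
#' Inverse of \code{\link{read_annotation_csv}}: one column per track (header
#' = subject id), one row per second.
#'
#' @param tracks a single \code{annotation_track} (single expert) or a list of
#'   them; multi-expert tracks are split into one column per expert with
#'   suffixed ids.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_csv <- function(tracks, path) {
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  cols <- list()
  for (tr in tracks) {
    if (!inherits(tr, "annotation_track")) stopf("all elements must be annotation_track")
    for (e in seq_len(nrow(tr$marks))) {
      id <- if (nrow(tr$marks) > 1) paste0(tr$subject_id, "_", LETTERS[e]) else tr$subject_id
      cols[[id]] <- tr$marks[e, ]
    }
  }
  len <- vapply(cols, length, integer(1))
  if (length(unique(len)) > 1) stopf("tracks have differing lengths: %s",
                                     paste(len, collapse = ", "))
  write.csv(as.data.frame(cols, check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Collapse multiple expert tracks into one consensus track
#'
#' @param tracks list of \code{annotation_track}s (or one multi-expert track)
#'   covering the same seconds.
#' @param rule consensus rule: \code{"any"} (logical OR across experts,
#'   default), \code{"majority"} (at least half, rounded up), or \code{"all"}
#'   (logical AND).
#' @return A single-expert consensus \code{annotation_track}.
#' @examples
#' a <- annotation_track(c(1, 0)); b <- annotation_track(c(1, 1))
#' c <- annotation_track(c(0, 0))
#' merge_expert_tracks(list(a, b, c), "majority")$marks
#' @export
merge_expert_tracks <- function(tracks, rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  if (!length(tracks)) stopf("no tracks to merge")
  mats <- lapply(tracks, function(tr) {
    if (!inherits(tr, "annotation_track")) stopf("all elements must be annotation_track")
    tr$marks
  })
  secs <- vapply(mats, ncol, integer(1))
  if (length(unique(secs)) > 1)
    stopf("tracks have differing lengths (seconds): %s", paste(secs, collapse = ", "))
  marks <- do.call(rbind, mats)
  n_exp <- nrow(marks)
  votes <- colSums(marks)
  consensus <- switch(rule,
    any      = as.integer(votes >= 1L),
    majority = as.integer(votes >= ceiling(n_exp / 2)),
    all      = as.integer(votes == n_exp))
  annotation_track(consensus, subject_id = tracks[[1]]$subject_id)
}
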