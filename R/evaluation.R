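# Beat-level evaluation: one-to-one matching of detections to reference
# annotations within a time tolerance, and the derived detection statistics.

#' Match detections to reference beats
#'
#' One-to-one matching within a time tolerance: reference beats are
#' traversed in order and each is paired with the earliest unmatched
#' detection within `tolerance_ms` (earliest-eligible greedy, which attains
#' the maximum possible number of pairs for interval tolerances). Unmatched
#' references are false negatives; unmatched detections are false
#' positives.
#'
#' @param detections sorted detection sample indices (raw coordinates).
#' @param reference a [beat_annotations()] object or a sorted numeric vector
#'   of reference sample indices.
#' @param fs sampling frequency in Hz.
#' @param tolerance_ms matching tolerance in ms (default 150, the ANSI/AAMI
#'   EC57 convention).
#' @return A list with `tp`, `fp`, `fn` counts and `pairs`, a data.frame of
#'   matched (reference, detection) index pairs.
#' @export
match_beats <- function(detections, reference, fs, tolerance_ms = 150) {
  if (tolerance_ms <= 0) stop("tolerance_ms must be positive")
  ref <- if (inherits(reference, "beat_annotations"))
    reference$indices else as.numeric(reference)
  det <- as.numeric(detections)
  if (is.unsorted(ref) || is.unsorted(det))
    stop("detections and reference indices must be sorted")
  tol <- tolerance_ms / 1000 * fs
  used <- logical(length(det))
  ref_match <- rep(NA_integer_, length(ref))
  j <- 1L
  for (i in seq_along(ref)) {
    while (j <= length(det) && (used[j] || det[j] < ref[i] - tol)) j <- j + 1L
    if (j <= length(det) && abs(det[j] - ref[i]) <= tol) {
      ref_match[i] <- j
      used[j] <- TRUE
    }
  }
  tp <- sum(!is.na(ref_match))
  list(tp = tp, fp = sum(!used), fn = sum(is.na(ref_match)),
       pairs = data.frame(reference = ref[!is.na(ref_match)],
                          detection = det[ref_match[!is.na(ref_match)]]))
}

#' Detection statistics from matched counts
#'
#' Computes the beat-detection figures of merit from true-positive,
#' false-positive and false-negative counts:
#' detection rate `(actual - (FP + FN)) / actual`, sensitivity
#' `Se = TP / (TP + FN)`, positive predictivity `Sp = TP / (TP + FP)`
#' (reported as "specificity" in parts of the QRS-detection literature),
#' and error rate `Er = (FP + FN) / actual`.
#'
#' @param tp,fp,fn non-negative counts.
#' @param actual reference beat count; must equal `tp + fn`.
#' @param record_id optional label.
#' @return A one-row data.frame of class `eval_result` with columns
#'   `record_id`, `actual`, `tp`, `fp`, `fn`, `detection_rate`, `se`, `sp`,
#'   `er`.
#' @export
#' @examples
#' score_detection(tp = 2272, fp = 0, fn = 1, actual = 2273)
score_detection <- function(tp, fp, fn, actual = tp + fn,
                            record_id = NA_character_) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (actual <= 0) stop("'actual' must be positive")
  if (tp + fn != actual) stop("inconsistent counts: tp + fn must equal actual")
  structure(
    data.frame(record_id = record_id, actual = actual, tp = tp, fp = fp,
               fn = fn,
               detection_rate = (actual - (fp + fn)) / actual,
               se = tp / (tp + fn),
               sp = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               er = (fp + fn) / actual),
    class = c("eval_result", "data.frame"))
}

#' Evaluate the detector on one annotated record
#'
#' Runs the full pipeline on the record, reduces its reference annotations
#' to true beat codes (see [wfdb_beat_codes()]) and scores the detections.
#'
#' @param record an [ecg_record()] carrying reference annotations.
#' @param config a [detector_config()].
#' @return An `eval_result` row; the full `detection_result` is attached as
#'   attribute `"detection"`.
#' @export
evaluate_record <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(record$annotations))
    stop("record has no reference annotations to evaluate against")
  ann <- record$annotations
  beats <- ann$indices[ann$codes %in% wfdb_beat_codes()]
  res <- detect_record(record, config)
  m <- match_beats(fiducials(res), beats, record$fs,
                   config$match_tolerance_ms)
  out <- score_detection(m$tp, m$fp, m$fn, actual = length(beats),
                         record_id = record$record_id)
  attr(out, "detection") <- res
  out
}

#' Batch evaluation over several records
#'
#' Evaluates each record (a path to a WFDB record or an [ecg_record()]) and
#' appends an aggregate row whose counts are the column sums and whose rates
#' are recomputed from those summed counts — never averaged across records.
#' Per-record failures are caught, reported as a warning, and excluded.
#'
#' @param records list of [ecg_record()] objects and/or WFDB record paths.
#' @param config a [detector_config()].
#' @param csv optional path; when given, the table is written as CSV with
#'   the layout `record_id, actual, tp, fp, fn, detection_rate, se, sp, er`.
#' @return An `eval_result` data.frame: one row per record plus a final
#'   `"aggregate"` row.
#' @export
evaluate_database <- function(records, config = detector_config(),
                              csv = NULL) {
  rows <- list()
  for (rec in records) {
    r <- tryCatch({
      if (is.character(rec))
        rec <- read_wfdb_record(rec, channel = config$channel)
      out <- evaluate_record(rec, config)
      attr(out, "detection") <- NULL
      out
    }, error = function(e) {
      warning("record failed and was excluded: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) stop("no record could be evaluated")
  tab <- do.call(rbind, rows)
  agg <- score_detection(sum(tab$tp), sum(tab$fp), sum(tab$fn),
                         actual = sum(tab$actual), record_id = "aggregate")
  tab <- rbind(tab, agg)
  class(tab) <- c("eval_result", "data.frame")
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}
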