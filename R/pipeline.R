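#' Run the full QRS detection pipeline on a record
#'
#' Convenience wrapper chaining [preprocess()], [find_candidate_peaks()],
#' [detect_qrs()] and [to_raw_fiducials()] with one configuration object.
#'
#' @param record an [ecg_record()].
#' @param config a [detector_config()].
#' @param trace if `TRUE`, keep the per-decision threshold trace.
#' @return A `detection_result` with raw fiducials; the intermediate
#'   `preprocessed_signal` is attached as attribute `"preprocessed"` and the
#'   candidate peaks as `"peaks"`.
#' @export
#' @examples
#' rec <- generate_synthetic(synthetic_spec(duration_s = 15, seed = 3))
#' res <- detect_record(rec)
#' res
detect_record <- function(record, config = detector_config(),
                          trace = FALSE) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "detector_config"))
  fs <- record$fs
  pre <- preprocess(record, channel = config$channel,
                    window_n = scale_n(config$window_n, fs))
  peaks <- find_candidate_peaks(pre$integrated, fs,
                                merge_n = config$merge_n,
                                forced_n = config$forced_n)
  res <- detect_qrs(peaks, pre$integrated, fs, config = config,
                    trace = trace)
  res <- to_raw_fiducials(res, pre, refine_n = config$refine_n)
  attr(res, "preprocessed") <- pre
  attr(res, "peaks") <- peaks
  res
}

#' Write detections as CSV
#'
#' Columns: `raw_index` (0-based sample), `time_s`, `via_searchback`.
#'
#' @param result a `detection_result` with raw fiducials.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(result, path) {
  stopifnot(inherits(result, "detection_result"))
  df <- data.frame(raw_index = result$detections$raw_index,
                   time_s = result$detections$raw_index / result$fs,
                   via_searchback = result$detections$via_searchback)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detections as WFDB annotations
#'
#' Converts a `detection_result` to a [beat_annotations()] object (all
#' beats coded `"N"`), ready for [write_wfdb_annotations()].
#'
#' @param result a `detection_result` with raw fiducials.
#' @return A [beat_annotations()] object.
#' @export
detections_as_annotations <- function(result) {
  beat_annotations(fiducials(result))
}
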