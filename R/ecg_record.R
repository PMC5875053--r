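#' ECG record container
#'
#' An `ecg_record` bundles one or more equal-length sample channels with their
#' sampling frequency and, optionally, reference beat annotations. It is the
#' input type of [preprocess()] and [detect_record()].
#'
#' @param channels numeric vector (single channel) or list of equal-length
#'   numeric vectors, in physical units (mV) or raw ADC counts.
#' @param fs sampling frequency in Hz (positive scalar).
#' @param record_id text label for the record.
#' @param channel_names optional character vector of channel labels.
#' @param annotations optional [beat_annotations()] object with reference
#'   beat positions.
#'
#' @return An object of class `ecg_record` with fields `record_id`, `fs`,
#'   `channels` (list of numeric vectors), `channel_names`, `annotations`.
#' @seealso [read_wfdb_record()], [generate_synthetic()]
#' @export
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1.2 * seq(0, 5, by = 1 / 360)), fs = 360)
#' rec
ecg_record <- function(channels, fs, record_id = "record",
                       channel_names = NULL, annotations = NULL) {
  if (is.numeric(channels)) channels <- list(channels)
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a numeric vector or a non-empty list of them")
  lens <- vapply(channels, length, integer(1))
  if (any(lens < 1L) || length(unique(lens)) != 1L)
    stop("all channels must have identical length >= 1")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  if (length(channel_names) != length(channels))
    stop("'channel_names' length must match number of channels")
  if (!is.null(annotations) && !inherits(annotations, "beat_annotations"))
    stop("'annotations' must be a beat_annotations object")
  structure(
    list(record_id = as.character(record_id)[1], fs = as.numeric(fs),
         channels = lapply(channels, as.numeric),
         channel_names = as.character(channel_names),
         annotations = annotations),
    class = "ecg_record")
}

#' Reference beat annotations
#'
#' Sample positions (0-based, strictly increasing) and per-beat type codes,
#' as read from a WFDB annotation file or produced by the synthetic
#' generator's ground truth.
#'
#' @param indices integer-valued sample positions, 0-based, strictly
#'   increasing.
#' @param codes character vector of annotation mnemonics (e.g. `"N"`,
#'   `"V"`), one per index. Defaults to `"N"`.
#' @return Object of class `beat_annotations` with fields `indices`, `codes`.
#' @export
beat_annotations <- function(indices, codes = rep("N", length(indices))) {
  indices <- as.numeric(indices)
  if (length(indices) && any(diff(indices) <= 0))
    stop("annotation indices must be strictly increasing")
  if (length(indices) && any(indices < 0))
    stop("annotation indices must be >= 0 (0-based)")
  codes <- as.character(codes)
  if (length(codes) != length(indices))
    stop("'codes' must have one entry per index")
  structure(list(indices = indices, codes = codes),
            class = "beat_annotations")
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<ecg_record> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$channels), n, x$fs, n / x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  if (!is.null(x$annotations))
    cat(sprintf("  annotations: %d (%s)\n", length(x$annotations$indices),
                paste(utils::head(unique(x$annotations$codes), 8), collapse = " ")))
  invisible(x)
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d annotations\n", length(x$indices)))
  if (length(x$indices)) {
    tab <- table(x$codes)
    cat("  codes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# Pick a channel from a record by 1-based index or by name; default first.
resolve_channel <- function(record, channel = NULL) {
  if (is.null(channel)) return(1L)
  if (is.character(channel)) {
    i <- match(channel, record$channel_names)
    if (is.na(i)) stop("unknown channel name: ", channel)
    return(i)
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > length(record$channels))
    stop("channel index out of range")
  channel
}

#' Read an ECG signal from a two-column CSV
#'
#' Ad-hoc plain-text input: a CSV with columns `sample_index,value` (header
#' optional). The sampling frequency is not stored in the file and must be
#' supplied.
#'
#' @param path CSV file path.
#' @param fs sampling frequency in Hz.
#' @param record_id label for the returned record.
#' @return An [ecg_record()] with a single channel.
#' @export
read_ecg_csv <- function(path, fs, record_id = basename(path)) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("sample_index", "value"))
  df <- df[order(df$sample_index), , drop = FALSE]
  ecg_record(df$value, fs = fs, record_id = record_id)
}
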