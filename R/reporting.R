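# Post-detection reporting: suspicious long-RR regions and RR-Lorenz
# (Poincare) plot data.

#' Find abnormally long RR intervals
#'
#' Flags every consecutive pair of detections whose RR interval exceeds
#' 1000 ms (strictly: an RR of exactly 1000 ms is normal). A prolonged gap
#' between detected beats can indicate a dropped beat, a pause or a
#' detection failure, and is reported for a cardiologist to inspect rather
#' than classified.
#'
#' @param result a `detection_result` with raw fiducials (see
#'   [to_raw_fiducials()]).
#' @param fs sampling frequency in Hz.
#' @param abnormal_rr_ms gap duration threshold in ms (default 1000).
#' @return A data.frame with columns `start_index`, `end_index` (raw-signal
#'   samples bounding the gap), `start_s`, `end_s`, `gap_ms`; zero rows when
#'   fewer than two detections exist or no gap qualifies.
#' @export
find_abnormal_regions <- function(result, fs, abnormal_rr_ms = 1000) {
  idx <- fiducials(result)
  empty <- data.frame(start_index = numeric(0), end_index = numeric(0),
                      start_s = numeric(0), end_s = numeric(0),
                      gap_ms = numeric(0))
  if (length(idx) < 2L) return(empty)
  rr_ms <- diff(idx) / fs * 1000
  k <- which(rr_ms > abnormal_rr_ms)
  if (!length(k)) return(empty)
  data.frame(start_index = idx[k], end_index = idx[k + 1L],
             start_s = idx[k] / fs, end_s = idx[k + 1L] / fs,
             gap_ms = rr_ms[k])
}

#' RR-Lorenz (Poincare) plot coordinates
#'
#' Pairs each RR interval with its successor: `x = RR(N)`, `y = RR(N + 1)`,
#' both in milliseconds. A steady rhythm collapses onto a single point on
#' the identity line; scattered clouds reveal beat-to-beat variability and
#' arrhythmia at a glance.
#'
#' @param result a `detection_result` with raw fiducials.
#' @param fs sampling frequency in Hz.
#' @return A data.frame with columns `x_ms`, `y_ms`; zero rows when fewer
#'   than 3 detections (2 RR intervals) exist.
#' @export
lorenz_points <- function(result, fs) {
  idx <- fiducials(result)
  if (length(idx) < 3L)
    return(data.frame(x_ms = numeric(0), y_ms = numeric(0)))
  rr_ms <- diff(idx) / fs * 1000
  k <- length(rr_ms)
  data.frame(x_ms = rr_ms[-k], y_ms = rr_ms[-1])
}

# Raw fiducials if available, integrated otherwise.
fiducials <- function(result) {
  stopifnot(inherits(result, "detection_result"))
  idx <- result$detections$raw_index
  if (!length(idx) || anyNA(idx)) idx <- result$detections$integrated_index
  idx
}

#' Render detection reports to files
#'
#' Writes, under `out_dir`: one PNG per abnormal region (integrated signal
#' with the final threshold level above, raw signal with detection marks
#' below, the region shaded), an RR-Lorenz scatter PNG, a `lorenz.csv` of
#' the plot coordinates, and a machine-readable `summary.json` (record id,
#' beat count, RR statistics, regions).
#'
#' @param record the analysed [ecg_record()].
#' @param result a `detection_result` with raw fiducials.
#' @param regions output of [find_abnormal_regions()].
#' @param lorenz output of [lorenz_points()].
#' @param out_dir output directory (created if missing).
#' @param window_s half-width, in seconds, of the context plotted around
#'   each region.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(record, result, regions, lorenz, out_dir,
                           window_s = 5) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(result, "detection_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir)
  }
  fs <- record$fs
  x <- record$channels[[1]]
  idx <- fiducials(result)
  written <- character(0)

  if (nrow(regions)) {
    pre <- attr(result, "preprocessed")
    for (r in seq_len(nrow(regions))) {
      f <- file.path(out_dir, sprintf("region_%02d.png", r))
      grDevices::png(f, width = 900, height = 600)
      lo <- max(regions$start_s[r] - window_s, 0)
      hi <- min(regions$end_s[r] + window_s, (length(x) - 1) / fs)
      sel <- seq(floor(lo * fs), ceiling(hi * fs)) + 1
      sel <- sel[sel >= 1 & sel <= length(x)]
      tt <- (sel - 1) / fs
      graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
      if (!is.null(pre)) {
        graphics::plot(tt, pre$integrated[sel], type = "l",
                       xlab = "time (s)", ylab = "integrated",
                       main = sprintf("suspicious region %d (gap %.0f ms)",
                                      r, regions$gap_ms[r]))
        graphics::abline(h = result$state$threshold, col = "red")
      } else {
        graphics::plot.new(); graphics::title("integrated signal unavailable")
      }
      graphics::rect(regions$start_s[r], graphics::par("usr")[3],
                     regions$end_s[r], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("green", 0.2), border = NA)
      graphics::plot(tt, x[sel], type = "l", xlab = "time (s)",
                     ylab = "ECG (mV)")
      near <- idx[idx / fs >= lo & idx / fs <= hi]
      graphics::points(near / fs, x[near + 1], col = "red", pch = 4)
      graphics::rect(regions$start_s[r], graphics::par("usr")[3],
                     regions$end_s[r], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("green", 0.2), border = NA)
      grDevices::dev.off()
      written <- c(written, f)
    }
  }

  f <- file.path(out_dir, "lorenz.png")
  grDevices::png(f, width = 600, height = 600)
  if (nrow(lorenz)) {
    lim <- range(c(lorenz$x_ms, lorenz$y_ms))
    graphics::plot(lorenz$x_ms, lorenz$y_ms, xlim = lim, ylim = lim,
                   xlab = "RR(N) (ms)", ylab = "RR(N+1) (ms)",
                   main = paste("RR-Lorenz plot:", record$record_id),
                   pch = 20, col = grDevices::adjustcolor("blue", 0.5))
    graphics::abline(0, 1, col = "grey")
  } else {
    graphics::plot.new(); graphics::title("too few RR intervals")
  }
  grDevices::dev.off()
  written <- c(written, f)

  f <- file.path(out_dir, "lorenz.csv")
  utils::write.csv(lorenz, f, row.names = FALSE)
  written <- c(written, f)

  rr_ms <- if (length(idx) >= 2) diff(idx) / fs * 1000 else numeric(0)
  summary <- list(
    record_id = record$record_id, fs = fs,
    n_detections = nrow(result$detections),
    n_searchback = sum(result$detections$via_searchback),
    n_abnormal_regions = nrow(regions),
    rr_mean_ms = if (length(rr_ms)) mean(rr_ms) else NA,
    rr_sd_ms = if (length(rr_ms) > 1) stats::sd(rr_ms) else NA,
    regions = regions)
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  written <- c(written, f)
  invisible(written)
}
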