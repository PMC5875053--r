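# Adaptive SPK/NPK threshold state machine with RR tracking and
# threshold-halving search-back.

recompute_threshold <- function(state, config) {
  state$threshold <- config$thr_spk_w * state$spk + config$thr_npk_w * state$npk
  state
}

#' Initialise the adaptive threshold state
#'
#' Sets the initial signal-peak estimate from the maximum of the first 300
#' samples (at 360 Hz; rescaled for other rates) of the integrated signal:
#' `SPK = 0.13 * M_VAL`, `NPK = 0.1 * SPK`,
#' `THRESHOLD = 0.25 * SPK + 0.75 * NPK`. Records shorter than the
#' initialisation window use every sample.
#'
#' @param integrated non-negative integrated signal (length >= 1).
#' @param fs sampling frequency in Hz.
#' @param config a [detector_config()].
#' @return An object of class `threshold_state` with fields `spk`, `npk`,
#'   `threshold`, `rr_buffer`, `ave_rr`, `last_qrs_index`.
#' @export
init_threshold_state <- function(integrated, fs, config = detector_config()) {
  if (!length(integrated)) stop("empty integrated signal")
  init_n <- min(scale_n(config$init_n, fs), length(integrated))
  m_val <- max(integrated[seq_len(init_n)])
  state <- structure(
    list(spk = config$spk_init_frac * m_val, npk = NA_real_,
         threshold = NA_real_, rr_buffer = numeric(0), ave_rr = NA_real_,
         last_qrs_index = NA_real_),
    class = "threshold_state")
  state$npk <- config$npk_frac * state$spk
  recompute_threshold(state, config)
}

#' Push an RR interval into the rolling average
#'
#' The most recent 10 accepted RR intervals are kept in a FIFO buffer;
#' `ave_rr` is their arithmetic mean (over however many are present while
#' the buffer fills).
#'
#' @param state a `threshold_state`.
#' @param new_rr RR interval in samples (> 0).
#' @param rr_buffer_len buffer capacity (default 10).
#' @return Updated `threshold_state`.
#' @export
update_ave_rr <- function(state, new_rr, rr_buffer_len = 10L) {
  if (!is.numeric(new_rr) || length(new_rr) != 1L || new_rr <= 0)
    stop("RR interval must be a positive scalar")
  buf <- c(state$rr_buffer, new_rr)
  if (length(buf) > rr_buffer_len)
    buf <- buf[(length(buf) - rr_buffer_len + 1L):length(buf)]
  state$rr_buffer <- buf
  state$ave_rr <- mean(buf)
  state
}

accept_peak <- function(state, index, amplitude, config) {
  state$spk <- config$smoothing_factor * amplitude +
    (1 - config$smoothing_factor) * state$spk
  if (!is.na(state$last_qrs_index)) {
    rr <- index - state$last_qrs_index
    if (rr > 0) state <- update_ave_rr(state, rr, config$rr_buffer_len)
  }
  state$last_qrs_index <- index
  recompute_threshold(state, config)
}

reject_peak <- function(state, amplitude, config) {
  state$npk <- config$smoothing_factor * amplitude +
    (1 - config$smoothing_factor) * state$npk
  recompute_threshold(state, config)
}

current_timeout <- function(state, timeout_n, rr_gap_factor) {
  if (length(state$rr_buffer) >= 1L)
    max(timeout_n, rr_gap_factor * state$ave_rr)
  else
    timeout_n
}

#' Classify candidate peaks with the adaptive threshold
#'
#' Traverses candidate peaks left to right. A peak above the current
#' THRESHOLD is accepted as a QRS complex and refreshes the signal-peak
#' estimate (`SPK <- 0.125 peak + 0.875 SPK`); otherwise it refreshes the
#' noise-peak estimate the same way. After every refresh the threshold is
#' recomputed as `0.25 SPK + 0.75 NPK`. Ties are rejected (strict
#' inequality).
#'
#' **Search-back:** whenever the gap since the last accepted QRS exceeds the
#' timeout — 400 samples (1111 ms at 360 Hz), or `1.5 * AVE_RR` once RR
#' intervals have been buffered, whichever is larger — SPK is halved, the
#' threshold recomputed, and the previously rejected candidates inside the
#' gap are re-scanned under the lowered threshold; the first one to clear it
#' is accepted and flagged `via_searchback`. Halving repeats while the gap
#' persists and a rejected candidate in the gap could still clear a further
#' lowered threshold.
#'
#' @param peaks a `candidate_peaks` data.frame from [find_candidate_peaks()]
#'   (sorted by index).
#' @param integrated the integrated signal the peaks came from.
#' @param fs sampling frequency in Hz.
#' @param state a `threshold_state` from [init_threshold_state()]; `NULL`
#'   initialises one.
#' @param config a [detector_config()].
#' @param trace if `TRUE`, a per-decision data.frame of threshold values is
#'   attached as `state_trace`.
#' @return An object of class `detection_result`: `detections` (data.frame
#'   with `integrated_index`, `raw_index` — filled by
#'   [to_raw_fiducials()] —, `amplitude`, `via_searchback`),
#'   `rr_intervals` (samples, in integrated coordinates until delay
#'   correction), `state` (final), and optionally `state_trace`.
#' @export
detect_qrs <- function(peaks, integrated, fs, state = NULL,
                       config = detector_config(), trace = FALSE) {
  stopifnot(inherits(config, "detector_config"))
  if (is.null(state)) state <- init_threshold_state(integrated, fs, config)
  if (nrow(peaks) && is.unsorted(peaks$index, strictly = TRUE))
    stop("candidate peaks must be sorted by strictly increasing index")
  timeout_n <- scale_n(config$timeout_n, fs)

  det_idx <- numeric(0); det_amp <- numeric(0); det_sb <- logical(0)
  rejected <- data.frame(index = numeric(0), amplitude = numeric(0))
  tr <- if (trace) vector("list", 0) else NULL
  note <- function(event, index, amplitude, accepted) {
    if (trace)
      tr[[length(tr) + 1L]] <<- data.frame(
        event = event, index = index, amplitude = amplitude,
        spk = state$spk, npk = state$npk, threshold = state$threshold,
        accepted = accepted)
  }

  add_detection <- function(index, amplitude, searchback) {
    det_idx <<- c(det_idx, index); det_amp <<- c(det_amp, amplitude)
    det_sb <<- c(det_sb, searchback)
  }

  searchback <- function(upto) {
    # halve SPK while the gap persists and a rejected candidate could still
    # clear a further-lowered threshold
    repeat {
      gap <- upto - state$last_qrs_index
      if (gap <= current_timeout(state, timeout_n, config$rr_gap_factor))
        break
      pool <- rejected[rejected$index > state$last_qrs_index &
                         rejected$index < upto, , drop = FALSE]
      if (!nrow(pool)) break
      # lowest threshold reachable by halving alone
      if (max(pool$amplitude) <= config$thr_npk_w * state$npk) break
      state$spk <<- config$searchback_halving * state$spk
      state <<- recompute_threshold(state, config)
      hit <- which(pool$amplitude > state$threshold)
      if (length(hit)) {
        k <- hit[1]
        state <<- accept_peak(state, pool$index[k], pool$amplitude[k], config)
        add_detection(pool$index[k], pool$amplitude[k], TRUE)
        rejected <<- rejected[rejected$index != pool$index[k], , drop = FALSE]
        note("searchback", pool$index[k], pool$amplitude[k], TRUE)
      }
    }
  }

  if (nrow(peaks)) {
    for (r in seq_len(nrow(peaks))) {
      p_idx <- peaks$index[r]; p_amp <- peaks$amplitude[r]
      if (!is.na(state$last_qrs_index)) searchback(p_idx)
      if (p_amp > state$threshold) {
        state <- accept_peak(state, p_idx, p_amp, config)
        add_detection(p_idx, p_amp, FALSE)
        note("peak", p_idx, p_amp, TRUE)
      } else {
        state <- reject_peak(state, p_amp, config)
        rejected <- rbind(rejected,
                          data.frame(index = p_idx, amplitude = p_amp))
        note("peak", p_idx, p_amp, FALSE)
      }
    }
    # final gap between the last QRS and the end of the record
    if (!is.na(state$last_qrs_index)) searchback(length(integrated))
  }

  # searchback insertions may arrive out of order; restore time order
  ord <- order(det_idx)
  detections <- data.frame(integrated_index = det_idx[ord],
                           raw_index = rep(NA_real_, length(ord)),
                           amplitude = det_amp[ord],
                           via_searchback = det_sb[ord])
  structure(
    list(detections = detections,
         rr_intervals = diff(detections$integrated_index),
         state = state,
         state_trace = if (trace) do.call(rbind, tr) else NULL,
         fs = fs, total_delay = NA_integer_),
    class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d QRS detections (%d via search-back) @ %g Hz\n",
              nrow(x$detections), sum(x$detections$via_searchback), x$fs))
  if (length(x$rr_intervals))
    cat(sprintf("  RR: mean %.1f ms, range [%.0f, %.0f] ms\n",
                mean(x$rr_intervals) / x$fs * 1000,
                min(x$rr_intervals) / x$fs * 1000,
                max(x$rr_intervals) / x$fs * 1000))
  invisible(x)
}

#' Map detections from integrated-signal to raw-signal coordinates
#'
#' Subtracts the cascade's total group delay from each integrated-signal
#' fiducial and, when `refine_n > 0`, snaps the result to the
#' largest-magnitude band-passed sample within `refine_n` samples, undoing
#' the residual misalignment left by startup transients and the rounded
#' integration delay. Indices are clamped to the signal bounds; ordering is
#' preserved.
#'
#' @param result a `detection_result` from [detect_qrs()].
#' @param pre the matching `preprocessed_signal`.
#' @param refine_n half-width of the snapping window in samples at 360 Hz
#'   (0 = pure delay subtraction).
#' @return The `detection_result` with `raw_index` filled and
#'   `rr_intervals` recomputed from raw fiducials.
#' @export
to_raw_fiducials <- function(result, pre, refine_n = 10L) {
  stopifnot(inherits(result, "detection_result"),
            inherits(pre, "preprocessed_signal"))
  n <- length(pre$raw)
  delay <- pre$total_delay
  bp_delay <- sum(pre$stage_delays[c("lowpass", "highpass")])
  refine_n <- if (refine_n > 0) scale_n(refine_n, pre$fs) else 0L
  raw_idx <- pmin(pmax(result$detections$integrated_index - delay, 0), n - 1)
  if (refine_n > 0L && nrow(result$detections)) {
    raw_idx <- vapply(raw_idx, function(ri) {
      # the band-passed sample aligned with raw index ri sits at ri + bp_delay
      ctr <- ri + bp_delay
      lo <- max(ctr - refine_n, 0); hi <- min(ctr + refine_n, n - 1)
      win <- pre$bandpassed[(lo:hi) + 1]
      (lo + which.max(abs(win)) - 1) - bp_delay
    }, numeric(1))
    raw_idx <- pmin(pmax(raw_idx, 0), n - 1)
  }
  result$detections$raw_index <- raw_idx
  result$total_delay <- delay
  result$rr_intervals <- diff(raw_idx)
  result
}
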