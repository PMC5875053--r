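#' Detector configuration
#'
#' Collects every tunable constant of the detection pipeline in one object.
#' Sample-count parameters are defined at the 360 Hz reference rate and
#' rescaled proportionally when a record uses a different sampling
#' frequency.
#'
#' @param window_n moving-integration window, samples at 360 Hz (24, i.e.
#'   66.7 ms).
#' @param init_n initialisation window for the threshold state, samples
#'   (300).
#' @param merge_n candidate-peak merge distance, samples (80, i.e. 222 ms).
#' @param forced_n peak-forcing interval in the candidate scan, samples
#'   (300).
#' @param timeout_n search-back timeout, samples (400, i.e. 1111 ms).
#' @param spk_init_frac initial signal-peak estimate as a fraction of the
#'   initialisation-window maximum (0.13).
#' @param npk_frac initial noise-peak estimate as a fraction of the signal
#'   peak (0.1).
#' @param thr_spk_w,thr_npk_w threshold weights on SPK and NPK (0.25 and
#'   0.75; must sum to 1).
#' @param searchback_halving factor applied to SPK on each search-back
#'   (0.5).
#' @param rr_gap_factor multiple of the average RR interval that triggers
#'   search-back (1.5).
#' @param rr_buffer_len number of recent RR intervals averaged (10).
#' @param smoothing_factor exponential-update weight of a new peak in the
#'   SPK/NPK running estimates (0.125).
#' @param abnormal_rr_ms RR duration above which a region is reported as
#'   suspicious (1000 ms, strict).
#' @param match_tolerance_ms beat-matching tolerance for evaluation (150 ms,
#'   the ANSI/AAMI EC57 convention).
#' @param refine_n half-width, in samples at 360 Hz, of the window used to
#'   snap delay-corrected fiducials onto the band-passed extremum (10).
#' @param channel channel name or index used for detection (default: first).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(window_n = 24L, init_n = 300L, merge_n = 80L,
                            forced_n = 300L, timeout_n = 400L,
                            spk_init_frac = 0.13, npk_frac = 0.1,
                            thr_spk_w = 0.25, thr_npk_w = 0.75,
                            searchback_halving = 0.5, rr_gap_factor = 1.5,
                            rr_buffer_len = 10L, smoothing_factor = 0.125,
                            abnormal_rr_ms = 1000, match_tolerance_ms = 150,
                            refine_n = 10L, channel = NULL) {
  counts <- c(window_n = window_n, init_n = init_n, merge_n = merge_n,
              forced_n = forced_n, timeout_n = timeout_n,
              rr_buffer_len = rr_buffer_len)
  if (any(counts < 1)) stop("all sample-count parameters must be positive")
  if (abs(thr_spk_w + thr_npk_w - 1) > 1e-12)
    stop("thr_spk_w + thr_npk_w must equal 1")
  fracs <- c(spk_init_frac = spk_init_frac, npk_frac = npk_frac,
             searchback_halving = searchback_halving,
             smoothing_factor = smoothing_factor)
  if (any(fracs <= 0 | fracs > 1))
    stop("fractional parameters must lie in (0, 1]")
  structure(
    list(window_n = as.integer(window_n), init_n = as.integer(init_n),
         merge_n = as.integer(merge_n), forced_n = as.integer(forced_n),
         timeout_n = as.integer(timeout_n), spk_init_frac = spk_init_frac,
         npk_frac = npk_frac, thr_spk_w = thr_spk_w, thr_npk_w = thr_npk_w,
         searchback_halving = searchback_halving,
         rr_gap_factor = rr_gap_factor,
         rr_buffer_len = as.integer(rr_buffer_len),
         smoothing_factor = smoothing_factor,
         abnormal_rr_ms = abnormal_rr_ms,
         match_tolerance_ms = match_tolerance_ms,
         refine_n = as.integer(refine_n), channel = channel),
    class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  ms <- function(n) sprintf("%d samples (%.1f ms at 360 Hz)", n, n / 0.36)
  cat("<detector_config>\n")
  cat("  integration window:  ", ms(x$window_n), "\n")
  cat("  init window:         ", x$init_n, "samples\n")
  cat("  peak merge distance: ", ms(x$merge_n), "\n")
  cat("  peak forcing:        ", x$forced_n, "samples\n")
  cat("  search-back timeout: ", ms(x$timeout_n), "or",
      x$rr_gap_factor, "x AVE_RR\n")
  cat(sprintf("  init: SPK = %.2f * max(init window), NPK = %.2f * SPK\n",
              x$spk_init_frac, x$npk_frac))
  cat(sprintf("  THRESHOLD = %.2f*SPK + %.2f*NPK; smoothing %.3f; halving %.2f\n",
              x$thr_spk_w, x$thr_npk_w, x$smoothing_factor,
              x$searchback_halving))
  cat(sprintf("  RR buffer %d; abnormal RR > %g ms; match tol %g ms\n",
              x$rr_buffer_len, x$abnormal_rr_ms, x$match_tolerance_ms))
  invisible(x)
}
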