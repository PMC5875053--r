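#' Find candidate QRS peaks in the integrated signal
#'
#' Single left-to-right scan over the (non-negative) integrated signal,
#' maintaining the running maximum since the last emitted peak:
#'
#' * **half-drop rule** — when the current sample falls below half the
#'   running maximum, the position of that maximum is emitted as a candidate
#'   peak and the running maximum restarts from the current sample;
#' * **forcing rule** — if no peak has been emitted for 300 samples (at
#'   360 Hz; rescaled for other rates), the local maximum of the unemitted
#'   stretch is emitted and flagged `forced`;
#' * **merge rule** — candidates closer than 80 samples (222 ms at 360 Hz)
#'   are merged iteratively, keeping the largest amplitude (ties keep the
#'   earlier peak), until all surviving peaks are at least the merge
#'   distance apart.
#'
#' Forced peaks on flat stretches are deliberately kept: rejecting them as
#' noise is the adaptive threshold's job, which keeps this stage
#' threshold-free.
#'
#' @param integrated non-negative numeric signal (output of
#'   [qrs_integrate()]).
#' @param fs sampling frequency in Hz.
#' @param merge_n,forced_n merge distance and forcing interval in samples at
#'   360 Hz (defaults 80 and 300); rescaled to `fs`.
#' @return A data.frame of class `candidate_peaks` with columns `index`
#'   (0-based sample position), `amplitude`, `forced` (logical).
#' @export
#' @examples
#' find_candidate_peaks(c(0, 1, 4, 9, 4, 1, 0), fs = 360)
find_candidate_peaks <- function(integrated, fs, merge_n = 80L,
                                 forced_n = 300L) {
  if (!length(integrated)) {
    return(structure(data.frame(index = integer(0), amplitude = numeric(0),
                                forced = logical(0)),
                     class = c("candidate_peaks", "data.frame")))
  }
  if (any(integrated < 0)) stop("integrated signal must be non-negative")
  merge_n <- scale_n(merge_n, fs)
  forced_n <- scale_n(forced_n, fs)
  n <- length(integrated)

  idx <- integer(0); amp <- numeric(0); forced <- logical(0)
  run_max <- -Inf; run_max_at <- 1L
  stretch_start <- 1L   # first sample not yet covered by an emitted peak
  last_emit_pos <- 0L   # scan position of the last emission (0 = none yet)

  for (i in seq_len(n)) {
    v <- integrated[i]
    if (v > run_max) { run_max <- v; run_max_at <- i }
    if (run_max > 0 && v < run_max / 2) {
      idx <- c(idx, run_max_at); amp <- c(amp, run_max)
      forced <- c(forced, FALSE)
      run_max <- v; run_max_at <- i
      stretch_start <- i
      last_emit_pos <- i
    } else if (i - last_emit_pos >= forced_n) {
      # no emission for a whole forcing interval: take the stretch's max
      seg <- integrated[stretch_start:i]
      at <- stretch_start + which.max(seg) - 1L
      idx <- c(idx, at); amp <- c(amp, integrated[at])
      forced <- c(forced, TRUE)
      run_max <- v; run_max_at <- i
      stretch_start <- i
      last_emit_pos <- i
    }
  }

  # iterative merge: collapse chains of close peaks to their single largest
  repeat {
    if (length(idx) < 2L) break
    gaps <- diff(idx)
    j <- which(gaps < merge_n)
    if (!length(j)) break
    j <- j[1]
    drop <- if (amp[j + 1] > amp[j]) j else j + 1L  # tie keeps the earlier
    idx <- idx[-drop]; amp <- amp[-drop]; forced <- forced[-drop]
  }

  structure(data.frame(index = idx - 1L, amplitude = amp, forced = forced),
            class = c("candidate_peaks", "data.frame"))
}
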