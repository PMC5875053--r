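# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (direct transcriptions of the rules, O(n^2) where that
# is simplest) so they stay independent of the implementations they check.

# A noise-free synthetic spec: regular rhythm, no drift/powerline/noise.
clean_spec <- function(duration_s = 30, heart_rate_bpm = 72, seed = 42, ...) {
  synthetic_spec(duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_frac = 0, drift_amp = 0, powerline_amp = 0,
                 noise_sd = 0, seed = seed, ...)
}

# Direct FIR convolution oracle (zero-padded history).
fir_filter <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    kmax <- min(length(h), i)
    y[i] <- sum(h[seq_len(kmax)] * x[i - seq_len(kmax) + 1L])
  }
  y
}

# Analytically expanded impulse responses of the two recursive filters.
lp_impulse <- c(1:6, 5:1)                      # (1 - z^-6)^2 / (1 - z^-1)^2
hp_impulse <- {h <- rep(-1, 32); h[17] <- 31; h}  # 32 z^-16 - 32-sample sum

# Symmetry centre of an impulse response, on a half-sample grid (0-based):
# the candidate centre minimising total pairwise asymmetry.
symmetry_center <- function(h) {
  nz <- which(h != 0) - 1L
  lo <- min(nz); hi <- max(nz)
  get <- function(i) {
    out <- numeric(length(i))
    ok <- i >= 0 & i < length(h)
    out[ok] <- h[i[ok] + 1L]
    out
  }
  cands <- seq(lo, hi, by = 0.5)
  asym <- vapply(cands, function(cc) {
    ks <- seq(0.5, max(cc - lo, hi - cc) + 1, by = 0.5)
    ks <- ks[(cc + ks) %% 1 == 0]
    sum(abs(get(cc + ks) - get(cc - ks)))
  }, numeric(1))
  cands[which.min(asym)]
}

# Naive transcription of the candidate-peak rules: half-drop emission,
# forcing after `forced_n` silent samples, then pairwise merge closer than
# `merge_n` keeping the larger (tie -> earlier), repeated until stable.
brute_find_peaks <- function(x, merge_n, forced_n) {
  peaks <- list()
  run_max <- -Inf
  run_at <- 1L
  unemitted_from <- 1L
  since_emit <- 0L
  for (i in seq_along(x)) {
    if (x[i] > run_max) { run_max <- x[i]; run_at <- i }
    since_emit <- since_emit + 1L
    emitted <- FALSE
    if (run_max > 0 && x[i] < 0.5 * run_max) {
      peaks[[length(peaks) + 1L]] <- list(at = run_at, amp = run_max,
                                          forced = FALSE)
      emitted <- TRUE
    } else if (since_emit >= forced_n) {
      seg <- unemitted_from:i
      at <- seg[which.max(x[seg])]
      peaks[[length(peaks) + 1L]] <- list(at = at, amp = x[at], forced = TRUE)
      emitted <- TRUE
    }
    if (emitted) {
      run_max <- x[i]; run_at <- i
      unemitted_from <- i
      since_emit <- 0L
    }
  }
  at <- vapply(peaks, `[[`, numeric(1), "at")
  amp <- vapply(peaks, `[[`, numeric(1), "amp")
  forced <- vapply(peaks, `[[`, logical(1), "forced")
  repeat {
    if (length(at) < 2L) break
    viol <- which(diff(at) < merge_n)
    if (!length(viol)) break
    i <- viol[1L]
    drop <- if (amp[i + 1L] > amp[i]) i else i + 1L
    at <- at[-drop]; amp <- amp[-drop]; forced <- forced[-drop]
  }
  data.frame(index = at - 1L, amplitude = amp, forced = forced)
}

# Exhaustive maximum one-to-one matching within tolerance (exponential;
# only for tiny instances).
brute_match_count <- function(ref, det, tol) {
  if (!length(ref) || !length(det)) return(0L)
  best <- brute_match_count(ref[-1], det, tol)
  for (j in seq_along(det)) {
    if (abs(det[j] - ref[1]) <= tol)
      best <- max(best, 1L + brute_match_count(ref[-1], det[-j], tol))
  }
  best
}

# Minimal detection_result around given raw fiducials, for reporting tests.
fake_result <- function(raw_index, fs) {
  structure(
    list(detections = data.frame(integrated_index = raw_index + 35,
                                 raw_index = raw_index,
                                 amplitude = rep(1, length(raw_index)),
                                 via_searchback = rep(FALSE, length(raw_index))),
         rr_intervals = diff(raw_index),
         state = list(threshold = 0.1),
         state_trace = NULL, fs = fs, total_delay = 35L),
    class = "detection_result")
}
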