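# Five-stage QRS preprocessing cascade: recursive low-pass, high-pass,
# five-point derivative, squaring, moving-window integration. The filters are
# the classic integer-coefficient recursions designed for 360 Hz ECG; the
# window-style constants (integration width, init window, merge distance,
# timeout) are defined at 360 Hz and rescaled proportionally elsewhere.

# Rescale a sample count defined at 360 Hz to another sampling rate.
scale_n <- function(n360, fs) max(1L, as.integer(round(n360 * fs / 360)))

#' Recursive low-pass filter
#'
#' Second-order comb-derived low-pass
#' `y(n) = 2 y(n-1) - y(n-2) + x(n) - 2 x(n-6) + x(n-12)`,
#' i.e. the FIR `(1 - z^-6)^2 / (1 - z^-1)^2` implemented recursively.
#' Missing history is treated as zero, so the first samples carry a startup
#' transient. DC gain is 36; the impulse response is the symmetric triangle
#' `1,2,...,6,...,2,1`.
#'
#' @param x numeric signal (length >= 1).
#' @return Filtered signal, same length as `x`.
#' @export
qrs_lowpass <- function(x) {
  if (!length(x)) stop("empty input signal")
  n <- length(x)
  xpad <- c(numeric(12), x)
  y <- numeric(n + 2)
  for (i in seq_len(n)) {
    y[i + 2] <- 2 * y[i + 1] - y[i] +
      xpad[i + 12] - 2 * xpad[i + 6] + xpad[i]
  }
  y[-(1:2)]
}

#' Recursive high-pass filter
#'
#' All-pass-minus-low-pass high-pass: with the auxiliary running sum
#' `s(n) = s(n-1) + x(n) - x(n-32)`, the output is
#' `y(n) = 32 x(n-16) - s(n)`. DC gain is 0; passband gain is 32. Missing
#' history is zero.
#'
#' @param x numeric signal (length >= 1).
#' @return Filtered signal, same length as `x`.
#' @export
qrs_highpass <- function(x) {
  if (!length(x)) stop("empty input signal")
  n <- length(x)
  xpad <- c(numeric(32), x)
  # running 32-sample sum, recursively
  s <- cumsum(xpad[33:(n + 32)] - xpad[1:n])
  32 * xpad[(33 - 16):(n + 32 - 16)] - s
}

#' Five-point derivative
#'
#' Centred derivative `y(n) = (1/8) [-x(n-2) - 2 x(n-1) + 2 x(n+1) + x(n+2)]`.
#' The two future samples make the textbook form non-causal; it is applied
#' here as the equivalent causal filter with its 2-sample delay reported in
#' the cascade's delay bookkeeping. Boundaries use zero-padded neighbours.
#'
#' @param x numeric signal (length >= 5).
#' @return Derivative signal, same length as `x` (causal alignment: sample
#'   `n` holds the derivative centred at `n - 2`).
#' @export
qrs_derivative <- function(x) {
  if (length(x) < 5L) stop("derivative needs at least 5 samples")
  n <- length(x)
  xpad <- c(numeric(4), x)
  idx <- seq_len(n)
  (-xpad[idx] - 2 * xpad[idx + 1] + 2 * xpad[idx + 3] + xpad[idx + 4]) / 8
}

#' Squaring
#'
#' Elementwise square, making all samples non-negative and emphasising the
#' steep QRS slopes over gentler P/T slopes.
#'
#' @param x numeric signal.
#' @return `x^2`.
#' @export
qrs_square <- function(x) x^2

#' Moving-window integration
#'
#' Causal moving average `y(n) = (1/N) sum_{k=0}^{N-1} x(n-k)` with
#' zero-padded history. The default width of 24 samples at 360 Hz (66.7 ms)
#' matches the duration of a wide QRS complex.
#'
#' @param x numeric signal.
#' @param window_n window width in samples (>= 1).
#' @return Integrated signal, same length as `x`.
#' @export
qrs_integrate <- function(x, window_n = 24L) {
  window_n <- as.integer(window_n)
  if (is.na(window_n) || window_n < 1L) stop("window_n must be >= 1")
  if (!length(x)) stop("empty input signal")
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - window_n, 0L)
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / window_n
}

#' Run the full preprocessing cascade on a record
#'
#' Chains low-pass, high-pass, derivative, squaring and moving-window
#' integration on one channel of an [ecg_record()], keeping every
#' intermediate stage and the per-stage group-delay bookkeeping needed to map
#' fiducials in the integrated signal back to raw-signal coordinates.
#'
#' The low-pass/high-pass delays are carried as 6 and 15 samples (their sum,
#' 21 samples, is the exact symmetry centre of the cascaded band-pass); the
#' causal derivative adds 2, squaring 0, and integration `floor(N/2)`.
#'
#' @param record an [ecg_record()].
#' @param channel channel name or index (default: first channel).
#' @param window_n integration window in samples; `NULL` uses 24 rescaled to
#'   the record's sampling rate.
#' @return An object of class `preprocessed_signal` with fields `fs`, `raw`,
#'   `lowpassed`, `bandpassed`, `derivative`, `squared`, `integrated`,
#'   `stage_delays` (named), `total_delay`, `window_n`.
#' @export
preprocess <- function(record, channel = NULL, window_n = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  ch <- resolve_channel(record, channel)
  x <- record$channels[[ch]]
  fs <- record$fs
  if (is.null(window_n)) window_n <- scale_n(24L, fs)
  lp <- qrs_lowpass(x)
  bp <- qrs_highpass(lp)
  dv <- qrs_derivative(bp)
  sq <- qrs_square(dv)
  mw <- qrs_integrate(sq, window_n)
  delays <- c(lowpass = 6L, highpass = 15L, derivative = 2L, squaring = 0L,
              integration = as.integer(window_n %/% 2L))
  structure(
    list(fs = fs, raw = x, lowpassed = lp, bandpassed = bp, derivative = dv,
         squared = sq, integrated = mw, stage_delays = delays,
         total_delay = sum(delays), window_n = as.integer(window_n)),
    class = "preprocessed_signal")
}

#' @export
print.preprocessed_signal <- function(x, ...) {
  cat(sprintf("<preprocessed_signal> %d samples @ %g Hz\n",
              length(x$raw), x$fs))
  cat(sprintf("  integration window: %d samples (%.1f ms)\n",
              x$window_n, 1000 * x$window_n / x$fs))
  cat(sprintf("  stage delays: %s; total %d samples\n",
              paste(sprintf("%s=%d", names(x$stage_delays), x$stage_delays),
                    collapse = " "),
              x$total_delay))
  invisible(x)
}

#' Dump all preprocessing stages to CSV
#'
#' Writes one column per stage (raw, lowpassed, bandpassed, derivative,
#' squared, integrated) for debugging and plotting.
#'
#' @param pre a `preprocessed_signal` from [preprocess()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stages_csv <- function(pre, path) {
  stopifnot(inherits(pre, "preprocessed_signal"))
  df <- data.frame(sample = seq_along(pre$raw) - 1L, raw = pre$raw,
                   lowpassed = pre$lowpassed, bandpassed = pre$bandpassed,
                   derivative = pre$derivative, squared = pre$squared,
                   integrated = pre$integrated)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
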