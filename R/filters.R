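#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter and applies it forward and backward
#' (`signal::filtfilt`) so landmark times are not lag-shifted. The effective
#' attenuation is that of the filter applied twice.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param cutoff Single cutoff (high/lowpass) or `c(low, high)` (bandpass), Hz.
#' @param mode One of `"highpass"`, `"lowpass"`, `"bandpass"`.
#' @param order Filter order (per pass).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_filter <- function(x, fs, cutoff,
                               mode = c("highpass", "lowpass", "bandpass"),
                               order = 4) {
  mode <- match.arg(mode)
  nyq <- fs / 2
  if (any(cutoff <= 0) || any(cutoff >= nyq))
    stopf("cutoff frequencies must lie strictly inside (0, fs/2)")
  if (mode == "bandpass") {
    if (length(cutoff) != 2L || cutoff[2] <= cutoff[1])
      stopf("bandpass needs cutoff = c(low, high) with low < high")
  } else if (length(cutoff) != 1L) {
    stopf("%s needs a single cutoff", mode)
  }
  type <- switch(mode, highpass = "high", lowpass = "low", bandpass = "pass")
  filt <- signal::butter(order, cutoff / nyq, type = type)
  as.numeric(signal::filtfilt(filt, x))
}

# analytic signal via FFT: zero negative frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a signal
#'
#' Magnitude of the analytic signal, smoothed with a centered moving average.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param smooth_ms Moving-average window, ms.
#' @return Non-negative envelope, same length as `x`.
#' @export
signal_envelope <- function(x, fs, smooth_ms = 20) {
  env <- Mod(analytic_signal(x))
  win <- max(1L, round(smooth_ms / 1000 * fs))
  if (win > length(x)) stopf("signal shorter than the smoothing window")
  if (win > 1L) {
    k <- rep(1 / win, win)
    sm <- stats::filter(env, k, sides = 2)
    # moving average leaves NAs at the edges; hold the first/last valid value
    sm <- as.numeric(sm)
    ok <- which(!is.na(sm))
    sm[seq_len(ok[1] - 1)] <- sm[ok[1]]
    sm[seq(ok[length(ok)] + 1, length.out = length(sm) - ok[length(ok)])] <- sm[ok[length(ok)]]
    env <- sm
  }
  pmax(env, 0)
}
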