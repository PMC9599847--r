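#' Short-time Fourier power spectrogram
#'
#' Hann-windowed, one-sided STFT power of a buffer. Power is scaled so the
#' summed spectrogram equals the total windowed-signal energy (per-frame
#' Parseval identity), which makes band/phase energy comparisons meaningful.
#'
#' @param b A `signal_buffer`.
#' @param window_s Analysis window, s (must be shorter than the buffer).
#' @param overlap_frac Fractional overlap between consecutive windows.
#' @return A list of class `lv_spectrogram`: `times` (frame centers, s),
#'   `freqs` (Hz), `power` (freqs x times matrix, >= 0).
#' @export
compute_spectrogram <- function(b, window_s = 2.0, overlap_frac = 0.75) {
  stopifnot(inherits(b, "signal_buffer"))
  n <- length(b$samples)
  win_n <- round(window_s * b$fs)
  if (win_n >= n) stopf("window_s must be shorter than the buffer")
  if (overlap_frac < 0 || overlap_frac >= 1) stopf("overlap_frac must be in [0, 1)")
  hop <- max(1L, round(win_n * (1 - overlap_frac)))
  starts <- seq(1L, n - win_n + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1)) # Hann
  frames <- vapply(starts, function(s) b$samples[s:(s + win_n - 1L)] * w,
                   numeric(win_n))
  X <- stats::mvfft(frames)
  n_half <- floor(win_n / 2) + 1L
  P <- Mod(X[seq_len(n_half), , drop = FALSE])^2 / win_n
  # fold negative frequencies into the one-sided spectrum
  if (win_n %% 2 == 0) {
    if (n_half > 2) P[2:(n_half - 1L), ] <- 2 * P[2:(n_half - 1L), ]
  } else {
    if (n_half > 1) P[2:n_half, ] <- 2 * P[2:n_half, ]
  }
  structure(list(times = (starts - 1 + win_n / 2) / b$fs,
                 freqs = (seq_len(n_half) - 1) * b$fs / win_n,
                 power = P),
            class = "lv_spectrogram")
}
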