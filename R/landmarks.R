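#' Detect S1 and S2 heart-sound events in a buffer
#'
#' High-passes the buffer, takes the smoothed amplitude envelope, and marks
#' envelope peaks above an adaptive threshold (`threshold_factor` times the
#' median envelope) separated by at least `min_separation_ms`. Peaks are
#' paired into (S1, S2) by the alternating-interval rule: within each beat the
#' shorter inter-peak gap is systole, and the peak opening a short gap is S1.
#'
#' @param b A `signal_buffer` of at least 5 s.
#' @param hp_cutoff High-pass cutoff, Hz.
#' @param min_separation_ms Refractory period between peaks, ms (200 ms allows
#'   heart rates up to 180 bpm when applied to alternating S1/S2 peaks).
#' @param threshold_factor Multiple of the median envelope used as the
#'   detection threshold.
#' @param smooth_ms Envelope smoothing window, ms.
#' @return A list with `s1_times`, `s2_times` (s, buffer-relative) and
#'   `quality_ok`. Fewer than 4 detected peaks flags the buffer low-quality
#'   with empty landmark lists rather than raising an error.
#' @export
detect_heart_sounds <- function(b, hp_cutoff = 15, min_separation_ms = 200,
                                threshold_factor = 3, smooth_ms = 20) {
  stopifnot(inherits(b, "signal_buffer"))
  if (length(b$samples) / b$fs < 5) stopf("buffer must be at least 5 s long")
  hp <- butterworth_filter(b$samples, b$fs, hp_cutoff, "highpass")
  env <- signal_envelope(hp, b$fs, smooth_ms = smooth_ms)
  thr <- threshold_factor * stats::median(env)
  low_quality <- list(s1_times = numeric(0), s2_times = numeric(0), quality_ok = FALSE)
  if (thr <= 0) return(low_quality)
  pk <- pracma::findpeaks(env, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_separation_ms / 1000 * b$fs)))
  if (is.null(pk) || nrow(pk) < 4) return(low_quality)
  pos <- sort(pk[, 2])
  times <- (pos - 1) / b$fs
  gaps <- diff(times)
  # alternating-interval rule, applied locally so a missed peak cannot flip
  # the pairing for the rest of the buffer: gaps alternate systole (short)
  # and diastole (long), so a gap below the median gap is systolic; the peak
  # opening a systolic gap is S1, the peak closing it is S2
  q <- stats::quantile(gaps, c(0.25, 0.75), names = FALSE)
  short <- gaps < (q[1] + q[2]) / 2
  s1 <- times[which(short)]
  s2 <- times[which(short) + 1L]
  if (length(s1) < 2) return(low_quality)
  list(s1_times = s1, s2_times = s2, quality_ok = TRUE)
}

#' Delimit inhale and exhale phases in a buffer
#'
#' Low-passes the buffer to isolate the respiration wave, then finds its
#' extrema with a minimum separation of 1 s: trough-to-peak segments are
#' inhale intervals, peak-to-trough segments exhale.
#'
#' @param b A `signal_buffer` long enough for at least two respiratory cycles.
#' @param lp_cutoff Low-pass cutoff, Hz.
#' @return A list with `inhale_intervals`, `exhale_intervals` (two-column
#'   matrices, s) and `quality_ok`; no usable extrema flags low quality.
#' @export
delimit_respiratory_phases <- function(b, lp_cutoff = 1) {
  stopifnot(inherits(b, "signal_buffer"))
  # demean first: filtfilt edge transients on a DC offset would otherwise
  # masquerade as respiratory oscillation
  lp <- butterworth_filter(b$samples - mean(b$samples), b$fs, lp_cutoff, "lowpass")
  minsep <- round(1 * b$fs)
  low_quality <- list(inhale_intervals = as_interval_matrix(NULL),
                      exhale_intervals = as_interval_matrix(NULL),
                      quality_ok = FALSE)
  # a (near-)constant buffer leaves only numerical ripple after filtering
  if (stats::sd(lp) <= 1e-9 * (1 + max(abs(b$samples)))) return(low_quality)
  floor_amp <- 0.1 * stats::sd(lp)
  peaks <- pracma::findpeaks(lp, minpeakdistance = minsep, minpeakheight = floor_amp)
  troughs <- pracma::findpeaks(-lp, minpeakdistance = minsep, minpeakheight = floor_amp)
  if (is.null(peaks) || is.null(troughs)) return(low_quality)
  ext <- rbind(cbind(peaks[, 2], +1), cbind(troughs[, 2], -1))
  ext <- ext[order(ext[, 1]), , drop = FALSE]
  # collapse runs of same-type extrema, keeping the more extreme one
  keep <- logical(nrow(ext))
  i <- 1L
  while (i <= nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext[j + 1, 2] == ext[i, 2]) j <- j + 1L
    run <- i:j
    best <- run[which.max(ext[run, 2] * lp[ext[run, 1]])]
    keep[best] <- TRUE
    i <- j + 1L
  }
  ext <- ext[keep, , drop = FALSE]
  if (nrow(ext) < 2) return(low_quality)
  tt <- (ext[, 1] - 1) / b$fs
  inh <- exh <- NULL
  for (k in seq_len(nrow(ext) - 1)) {
    if (ext[k, 2] == -1) inh <- rbind(inh, c(tt[k], tt[k + 1]))
    else exh <- rbind(exh, c(tt[k], tt[k + 1]))
  }
  list(inhale_intervals = as_interval_matrix(inh),
       exhale_intervals = as_interval_matrix(exh),
       quality_ok = !is.null(inh) && !is.null(exh))
}

#' Detect all landmarks in a buffer
#'
#' Runs [detect_heart_sounds()] and [delimit_respiratory_phases()] and bundles
#' the result; the buffer is flagged low-quality if either stage is.
#'
#' @param b A `signal_buffer`.
#' @param hp_cutoff,lp_cutoff,min_separation_ms,threshold_factor,smooth_ms
#'   Passed through to the detectors.
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(b, hp_cutoff = 15, lp_cutoff = 1,
                             min_separation_ms = 200, threshold_factor = 3,
                             smooth_ms = 20) {
  hs <- detect_heart_sounds(b, hp_cutoff = hp_cutoff,
                            min_separation_ms = min_separation_ms,
                            threshold_factor = threshold_factor,
                            smooth_ms = smooth_ms)
  rp <- delimit_respiratory_phases(b, lp_cutoff = lp_cutoff)
  landmark_set(s1_times = hs$s1_times, s2_times = hs$s2_times,
               inhale_intervals = rp$inhale_intervals,
               exhale_intervals = rp$exhale_intervals,
               quality_ok = hs$quality_ok && rp$quality_ok)
}
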