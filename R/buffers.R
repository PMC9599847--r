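#' Split a measurement into overlapping buffers
#'
#' Cuts the recording into full-length windows of `buffer_s` seconds starting
#' at multiples of `step_s` (50% overlap at the defaults). Partial windows are
#' never emitted; the buffer count is
#' `floor((duration - buffer_s) / step_s) + 1`.
#'
#' @param m A `vibration_measurement`.
#' @param buffer_s Window length, s.
#' @param step_s Hop between window starts, s.
#' @return A list of `signal_buffer` objects (`measurement_id`, `start_time`,
#'   `fs`, `samples`).
#' @export
split_buffers <- function(m, buffer_s = 60, step_s = 30) {
  stopifnot(inherits(m, "vibration_measurement"))
  duration <- length(m$samples) / m$fs
  if (buffer_s > duration + 1e-9) stopf("buffer_s (%g s) exceeds the recording (%g s)", buffer_s, duration)
  if (step_s <= 0) stopf("step_s must be positive")
  n_buf <- floor((duration - buffer_s) / step_s + 1e-9) + 1
  lapply(seq_len(n_buf), function(i) {
    start <- (i - 1) * step_s
    i0 <- round(start * m$fs) + 1L
    i1 <- i0 + round(buffer_s * m$fs) - 1L
    structure(list(measurement_id = m$measurement_id, start_time = start,
                   fs = m$fs, samples = m$samples[i0:i1]),
              class = "signal_buffer")
  })
}

# restrict a landmark_set to a buffer's time window, re-based to buffer time
crop_landmarks <- function(lm, start, duration) {
  clip_iv <- function(iv) {
    if (nrow(iv) == 0L) return(iv)
    lo <- pmax(iv[, 1] - start, 0)
    hi <- pmin(iv[, 2] - start, duration)
    keep <- hi > lo
    cbind(lo[keep], hi[keep])
  }
  keep1 <- lm$s1_times >= start & lm$s1_times < start + duration
  keep2 <- lm$s2_times >= start & lm$s2_times < start + duration
  landmark_set(s1_times = lm$s1_times[keep1] - start,
               s2_times = lm$s2_times[keep2] - start,
               inhale_intervals = clip_iv(lm$inhale_intervals),
               exhale_intervals = clip_iv(lm$exhale_intervals),
               quality_ok = lm$quality_ok)
}

# crop a measurement to its first `duration_s` seconds (duration-sweep support)
crop_measurement <- function(m, duration_s) {
  n <- round(duration_s * m$fs)
  if (n > length(m$samples)) stopf("measurement %s shorter than %g s", m$measurement_id, duration_s)
  out <- m
  out$samples <- m$samples[seq_len(n)]
  if (!is.null(m$truth_landmarks))
    out$truth_landmarks <- crop_landmarks(m$truth_landmarks, 0, duration_s)
  out
}
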