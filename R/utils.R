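# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic per-measurement RNG seed
#'
#' Hashes a base seed together with subject and measurement identifiers into a
#' 31-bit integer, so any single measurement can be regenerated without
#' replaying the whole cohort stream.
#'
#' @param seed Base integer seed.
#' @param subject_id,measurement_id Identifier strings.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
measurement_seed <- function(seed, subject_id, measurement_id) {
  key <- paste(subject_id, measurement_id, sep = "\r")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    # 31-bit multiplicative hash; constants from the classic Park-Miller family
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# validate a scalar numeric in an open/closed range
check_scalar <- function(x, name, lo = -Inf, hi = Inf, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lo || (open_lo && x <= lo)) stopf("'%s' must be %s %s", name, if (open_lo) ">" else ">=", lo)
  if (x > hi || (open_hi && x >= hi)) stopf("'%s' must be %s %s", name, if (open_hi) "<" else "<=", hi)
  invisible(x)
}

# intervals are n x 2 matrices [start, end); helpers used by landmarks/features
as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), ncol = 2))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2)
    return(unname(x))
  }
  do.call(rbind, lapply(x, function(iv) matrix(as.numeric(iv), ncol = 2)))
}

# TRUE for time points falling inside any [start, end) interval
in_intervals <- function(t, intervals) {
  intervals <- as_interval_matrix(intervals)
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals[i, 1] & t < intervals[i, 2])
  hit
}
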