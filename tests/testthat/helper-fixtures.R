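# shared fixtures and independent oracles for the test suite

clean_subject <- function(id = "S1", congested = FALSE) {
  list(subject_id = id, congested = congested,
       respiratory_condition = FALSE, valvular_disorder = FALSE)
}

# a quiet, short measurement for landmark/feature tests
make_measurement <- function(duration = 60, congested = FALSE,
                             congestion_effect = 0, seed = 1, ...) {
  cfg <- signal_model_config(duration = duration,
                             congestion_effect = congestion_effect,
                             seed = seed, ...)
  synthesize_measurement(clean_subject(congested = congested), cfg)
}

as_buffer <- function(samples, fs, id = "T1") {
  structure(list(measurement_id = id, start_time = 0, fs = fs, samples = samples),
            class = "signal_buffer")
}

# fraction of reference events matched by a detection within tol seconds
match_fraction <- function(detected, reference, tol) {
  if (length(reference) == 0) return(NA_real_)
  mean(vapply(reference, function(t) any(abs(detected - t) <= tol), logical(1)))
}

# ---- independent oracles ----------------------------------------------------

# brute-force best stump: scan every feature, every candidate threshold,
# both polarities, computing the weighted error by direct prediction
oracle_stump <- function(X, y, w) {
  best <- list(eps = Inf)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    for (t in thr) for (pol in c(1, -1)) {
      pred <- ifelse(X[, j] > t, pol, -pol)
      eps <- sum(w[pred != y])
      if (eps < best$eps - 1e-12) best <- list(eps = eps, j = j, t = t, pol = pol)
    }
  }
  best
}

# independent discrete AdaBoost built directly from the textbook recursion
oracle_adaboost <- function(X, y, n_rounds, eps_floor = 1e-10) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  out <- list()
  for (t in seq_len(n_rounds)) {
    st <- oracle_stump(X, y, w)
    if (st$eps >= 0.5) break
    alpha <- 0.5 * log((1 - st$eps) / max(st$eps, eps_floor))
    out[[t]] <- c(j = st$j, thr = st$t, pol = st$pol, alpha = alpha, eps = st$eps)
    if (st$eps <= eps_floor) break
    pred <- ifelse(X[, st$j] > st$t, st$pol, -st$pol)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  do.call(rbind, out)
}

# AUC as the Mann-Whitney U probability, by direct pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == TRUE]
  neg <- scores[!(labels == 1 | labels == TRUE)]
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  amin <- max(0, n1 - m2); amax <- min(m1, n1)
  probs <- vapply(amin:amax, function(x)
    exp(lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)), numeric(1))
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# KS D by scanning the ECDF difference at every pooled point
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}
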