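#' Fit the best decision stump under sample weights
#'
#' Exhaustively searches features x candidate thresholds x polarity for the
#' stump minimizing weighted 0-1 error. Candidate thresholds per feature are
#' the midpoints of adjacent sorted unique values plus one threshold below the
#' minimum and one above the maximum (the constant stumps). A stump predicts
#' `polarity` where `x > threshold` and `-polarity` elsewhere. Ties are broken
#' toward the lower feature index, then the lower threshold.
#'
#' @param X Numeric matrix (rows = examples, named columns = features).
#' @param y Labels in `{-1, +1}`.
#' @param w Non-negative sample weights summing to 1.
#' @return A list of class `decision_stump`: `feature`, `feature_index`,
#'   `threshold`, `polarity`, `epsilon` (its weighted error).
#' @export
fit_stump <- function(X, y, w = rep(1 / length(y), length(y))) {
  stopifnot(is.matrix(X), all(y %in% c(-1, 1)))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) stopf("weights must be non-negative and sum to 1")
  n <- nrow(X)
  best <- list(epsilon = Inf, feature_index = NA_integer_, threshold = NA_real_, polarity = NA_real_)
  w_pos <- sum(w[y == 1])
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]; ys <- y[ord]; ws <- w[ord]
    # err(+1, t) = P(y=+1, x<=t) + P(y=-1, x>t); evaluated after each position
    cum_pos <- cumsum(ws * (ys == 1))
    cum_neg <- cumsum(ws * (ys == -1))
    w_neg <- 1 - w_pos
    err_after <- cum_pos + (w_neg - cum_neg) # length n: threshold after sample i
    err_pos <- c(w_neg, err_after)           # position 0 = predict everything +pol
    boundary <- c(TRUE, xs[-1] != xs[-n])    # distinct-value boundaries
    cand_pos <- which(c(boundary, TRUE))     # positions 0..n, 1-based index
    thr_at <- function(pos) {                # pos in 0..n
      if (pos == 0) xs[1] - 1
      else if (pos == n) xs[n] + 1
      else (xs[pos] + xs[pos + 1]) / 2
    }
    for (pos1 in cand_pos) {
      pos <- pos1 - 1L
      for (pol in c(1, -1)) {
        eps <- if (pol == 1) err_pos[pos1] else 1 - err_pos[pos1]
        th <- thr_at(pos)
        if (eps < best$epsilon - 1e-12 ||
            (abs(eps - best$epsilon) <= 1e-12 &&
             (j < best$feature_index ||
              (j == best$feature_index && th < best$threshold)))) {
          best <- list(epsilon = eps, feature_index = j, threshold = th, polarity = pol)
        }
      }
    }
  }
  structure(list(feature = colnames(X)[best$feature_index] %||% as.character(best$feature_index),
                 feature_index = best$feature_index,
                 threshold = best$threshold, polarity = best$polarity,
                 epsilon = best$epsilon),
            class = "decision_stump")
}

stump_predict <- function(stump, X) {
  x <- if (is.matrix(X)) X[, stump$feature] else X[[stump$feature]]
  ifelse(x > stump$threshold, stump$polarity, -stump$polarity)
}

#' Train a discrete AdaBoost ensemble of decision stumps
#'
#' Classic discrete AdaBoost: uniform initial weights; each round fits the
#' best stump, sets `alpha_t = 0.5 * log((1 - eps_t) / max(eps_t, eps_floor))`,
#' reweights `w_i <- w_i * exp(-alpha_t * y_i * h_t(x_i))` and renormalizes.
#' Training stops early when a round's weighted error reaches 0.5 (stump
#' rejected) or 0 (stump accepted with capped alpha, then stop).
#'
#' @param X Numeric feature matrix with column names; no missing values.
#' @param y Labels in `{-1, +1}` (or logical/0-1, coerced); both classes
#'   required.
#' @param n_rounds Maximum boosting rounds T.
#' @param eps_floor Floor on the weighted error inside the alpha formula.
#' @return A list with `model` (class `stump_ensemble`: `stumps`, `n_rounds`,
#'   `selected_features`, and `operating_threshold`/`na_zone` slots filled by
#'   [select_operating_point()] / [calibrate_na_zone()]) and `trace`
#'   (data.frame with per-round `epsilon`, `alpha`, `loss_bound`).
#' @export
train_adaboost <- function(X, y, n_rounds = 50, eps_floor = 1e-10) {
  y <- to_pm1(y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  if (any(is.na(X))) stopf("feature matrix contains missing values; impute first")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  eps_v <- alpha_v <- bound_v <- numeric(0)
  for (t in seq_len(n_rounds)) {
    stump <- fit_stump(X, y, w)
    eps <- stump$epsilon
    if (eps >= 0.5) break
    alpha <- 0.5 * log((1 - eps) / max(eps, eps_floor))
    stump$alpha <- alpha
    stumps[[length(stumps) + 1L]] <- stump
    eps_v <- c(eps_v, eps); alpha_v <- c(alpha_v, alpha)
    bound_v <- c(bound_v, prod(2 * sqrt(pmax(eps_v, eps_floor) * (1 - eps_v))))
    if (eps <= eps_floor) break
    h <- stump_predict(stump, X)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  if (length(stumps) == 0) stopf("no stump achieved weighted error below 0.5")
  model <- structure(list(
    stumps = stumps,
    n_rounds = length(stumps),
    selected_features = unique(vapply(stumps, `[[`, character(1), "feature")),
    operating_threshold = NA_real_,
    na_zone = c(NA_real_, NA_real_)
  ), class = "stump_ensemble")
  list(model = model,
       trace = data.frame(round = seq_along(eps_v), epsilon = eps_v,
                          alpha = alpha_v, loss_bound = bound_v))
}

to_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  u <- sort(unique(y))
  if (all(u %in% c(-1, 1))) return(as.numeric(y))
  if (all(u %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  stopf("labels must be logical, 0/1 or -1/+1")
}

#' Score measurements with a stump ensemble
#'
#' Maps the normalized weighted vote (margin in `[-1, 1]`) affinely to a
#' congestion score in `[0, 1]`: `score = (margin + 1) / 2` with
#' `margin = sum(alpha_t h_t(x)) / sum(alpha_t)`. Scores near 1 indicate a
#' congested (case) pattern, near 0 a control pattern.
#'
#' @param model A `stump_ensemble`.
#' @param X Feature matrix or data.frame containing every selected feature.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
score_measurements <- function(model, X) {
  stopifnot(inherits(model, "stump_ensemble"))
  have <- if (is.matrix(X)) colnames(X) else names(X)
  missing_f <- setdiff(model$selected_features, have)
  if (length(missing_f)) stopf("missing selected feature(s): %s", paste(missing_f, collapse = ", "))
  alphas <- vapply(model$stumps, `[[`, numeric(1), "alpha")
  votes <- do.call(cbind, lapply(model$stumps, function(s) stump_predict(s, X)))
  margin <- as.numeric(votes %*% alphas) / sum(alphas)
  (margin + 1) / 2
}

#' Select the operating threshold at maximal balanced accuracy
#'
#' Scans thresholds midway between adjacent sorted unique scores, plus 0 and
#' 1, and returns the one maximizing `(sensitivity + specificity) / 2` under
#' the convention `score >= theta` means case. Ties go to the threshold
#' closest to 0.5.
#'
#' @param scores Scores in `[0, 1]`.
#' @param labels Case indicators (logical/0-1).
#' @return The selected threshold `theta`.
#' @export
select_operating_point <- function(scores, labels) {
  y <- to_pm1(labels) == 1
  if (!any(y) || all(y)) stopf("both classes are required to select an operating point")
  u <- sort(unique(scores))
  cand <- unique(sort(c(0, 1, (u[-1] + u[-length(u)]) / 2)))
  bal <- vapply(cand, function(th) {
    pred <- scores >= th
    (mean(pred[y]) + mean(!pred[!y])) / 2
  }, numeric(1))
  best <- which(bal >= max(bal) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

#' Calibrate the inconclusive (NA) zone around the operating threshold
#'
#' Scans symmetric half-widths `w` on a fixed grid (0 to 0.25 by 0.005) and
#' keeps the largest `w` such that (a) at most `max_na_frac` of the
#' calibration scores fall strictly inside `(theta - w, theta + w)` and
#' (b) the balanced accuracy on the remaining conclusive scores is no worse
#' than with no zone at all.
#'
#' @param scores Calibration scores.
#' @param labels Case indicators.
#' @param theta Operating threshold.
#' @param max_na_frac Largest tolerated inconclusive fraction.
#' @return `c(lo, hi)`, the open inconclusive interval.
#' @export
calibrate_na_zone <- function(scores, labels, theta, max_na_frac = 0.05) {
  check_scalar(max_na_frac, "max_na_frac", 0, 1, open_hi = TRUE)
  y <- to_pm1(labels) == 1
  bal_acc <- function(keep) {
    if (!any(keep) || !any(y[keep]) || all(y[keep])) return(-Inf)
    pred <- scores[keep] >= theta
    (mean(pred[y[keep]]) + mean(!pred[!y[keep]])) / 2
  }
  base <- bal_acc(rep(TRUE, length(scores)))
  w_best <- 0
  for (w in seq(0, 0.25, by = 0.005)) {
    inside <- scores > theta - w & scores < theta + w
    if (mean(inside) > max_na_frac) next
    if (w > 0 && bal_acc(!inside) < base) next
    if (w > w_best) w_best <- w
  }
  c(theta - w_best, theta + w_best)
}

#' Classify measurements with a calibrated model
#'
#' @param model A `stump_ensemble` with `operating_threshold` and `na_zone`
#'   set.
#' @param X Feature matrix/data.frame with the selected features.
#' @param measurement_id Optional ids carried into the output.
#' @return A data.frame (`measurement_id`, `score`, `decision`); `decision`
#'   is `"inconclusive"` iff the score falls strictly inside the NA zone,
#'   otherwise `"case"` when `score >= operating_threshold`, else
#'   `"control"`.
#' @export
classify_measurements <- function(model, X, measurement_id = NULL) {
  if (is.na(model$operating_threshold))
    stopf("model is not calibrated: set operating_threshold and na_zone first")
  s <- score_measurements(model, X)
  zone <- model$na_zone
  decision <- ifelse(s > zone[1] & s < zone[2], "inconclusive",
                     ifelse(s >= model$operating_threshold, "case", "control"))
  data.frame(measurement_id = measurement_id %||% seq_along(s),
             score = s, decision = decision, stringsAsFactors = FALSE)
}

#' Serialize / restore a stump ensemble as JSON
#'
#' @param model A `stump_ensemble`.
#' @param path File path.
#' @return `model_from_json` returns the restored `stump_ensemble`, which
#'   reproduces scores bit-identically.
#' @export
model_to_json <- function(model, path) {
  stumps <- lapply(model$stumps, function(s)
    list(feature = s$feature, threshold = s$threshold,
         polarity = s$polarity, alpha = s$alpha, epsilon = s$epsilon))
  jsonlite::write_json(list(stumps = stumps,
                            operating_threshold = model$operating_threshold,
                            na_zone = as.numeric(model$na_zone)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stumps <- lapply(obj$stumps, function(s) {
    s$feature_index <- NA_integer_
    structure(s, class = "decision_stump")
  })
  structure(list(
    stumps = stumps, n_rounds = length(stumps),
    selected_features = unique(vapply(stumps, `[[`, character(1), "feature")),
    operating_threshold = as.numeric(obj$operating_threshold),
    na_zone = as.numeric(unlist(obj$na_zone))
  ), class = "stump_ensemble")
}
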