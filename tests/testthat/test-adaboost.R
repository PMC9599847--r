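test_that("fit_stump matches hand-derived solutions on canonical inputs", {
  X <- matrix(1:4, ncol = 1, dimnames = list(NULL, "f"))
  sep <- fit_stump(X, c(-1, -1, 1, 1))
  expect_equal(sep$threshold, 2.5)
  expect_equal(sep$epsilon, 0)

  alt <- fit_stump(X, c(1, -1, 1, -1))
  expect_equal(alt$epsilon, 0.25)

  w <- c(1, 0, 0, 0)
  conc <- fit_stump(X, c(1, -1, 1, -1), w)
  expect_true(conc$epsilon %in% c(0, 1))
  expect_equal(conc$epsilon, 0) # some stump classifies the single weighted point
})

test_that("fit_stump equals exhaustive search on random weighted problems", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    p <- sample(1:3, 1)
    X <- matrix(sample(1:5, n * p, replace = TRUE), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    w <- stats::runif(n); w <- w / sum(w)
    expect_equal(fit_stump(X, y, w)$epsilon, oracle_stump(X, y, w)$eps,
                 tolerance = 1e-12)
  }
})

test_that("AdaBoost reproduces the textbook recursion and its loss bound", {
  set.seed(11)
  # ties-free continuous features so the stump sequence is unambiguous
  X <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + stats::rnorm(20, 0, 0.5) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  fit <- train_adaboost(X, y, n_rounds = 10)
  ref <- oracle_adaboost(X, y, n_rounds = 10)
  expect_equal(fit$model$n_rounds, nrow(ref))
  for (t in seq_len(nrow(ref))) {
    expect_equal(fit$model$stumps[[t]]$threshold, unname(ref[t, "thr"]), tolerance = 1e-9)
    expect_equal(fit$model$stumps[[t]]$alpha, unname(ref[t, "alpha"]), tolerance = 1e-9)
  }
  # Freund-Schapire: training error bounded by prod 2 sqrt(eps (1 - eps))
  pred <- ifelse(score_measurements(fit$model, X) >= 0.5, 1, -1)
  expect_lte(mean(pred != y), fit$trace$loss_bound[nrow(fit$trace)] + 1e-12)
  expect_true(all(diff(fit$trace$loss_bound) <= 1e-12))
  expect_true(all(fit$trace$epsilon < 0.5))
  expect_true(all(fit$trace$alpha > 0))
})

test_that("AdaBoost drives training error to zero on learnable toy sets", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "f"))
  fit <- train_adaboost(X, c(-1, -1, 1, 1))
  expect_equal(fit$model$n_rounds, 1)
  expect_equal(fit$trace$epsilon[1], 0)

  # interaction structure no single stump solves
  X2 <- cbind(a = c(0, 0.1, 1, 1.1), b = c(0, 1, 0.05, 1))
  y2 <- c(-1, 1, 1, -1)
  fit2 <- train_adaboost(X2, y2, n_rounds = 8)
  pred2 <- ifelse(score_measurements(fit2$model, X2) >= 0.5, 1, -1)
  expect_equal(mean(pred2 != y2), 0)

  expect_error(train_adaboost(X, c(1, 1, 1, 1)), "single class")
})

test_that("scores are the affine margin map and respect vote monotonicity", {
  stump <- function(thr, pol, alpha) structure(
    list(feature = "f", threshold = thr, polarity = pol, alpha = alpha),
    class = "decision_stump")
  model <- structure(list(stumps = list(stump(0, 1, 1), stump(0, 1, 2)),
                          n_rounds = 2, selected_features = "f",
                          operating_threshold = NA_real_, na_zone = c(NA, NA)),
                     class = "stump_ensemble")
  X <- matrix(c(5, -5), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(score_measurements(model, X), c(1, 0))

  disagree <- structure(list(stumps = list(stump(0, 1, 1), stump(0, -1, 1)),
                             n_rounds = 2, selected_features = "f",
                             operating_threshold = NA_real_, na_zone = c(NA, NA)),
                        class = "stump_ensemble")
  expect_equal(score_measurements(disagree, X), c(0.5, 0.5))

  # adding a case-voting stump never decreases any score
  set.seed(12)
  for (i in 1:10) {
    alphas <- stats::runif(3)
    base <- structure(list(stumps = list(stump(-1, 1, alphas[1]), stump(1, -1, alphas[2])),
                           n_rounds = 2, selected_features = "f",
                           operating_threshold = NA_real_, na_zone = c(NA, NA)),
                      class = "stump_ensemble")
    more <- base
    more$stumps[[3]] <- stump(-10, 1, alphas[3]) # votes case for all x > -10
    Xr <- matrix(stats::runif(5, -5, 5), ncol = 1, dimnames = list(NULL, "f"))
    expect_true(all(score_measurements(more, Xr) >= score_measurements(base, Xr) - 1e-12))
  }

  expect_error(score_measurements(model, matrix(1, dimnames = list(NULL, "g"))), "missing")
})

test_that("operating point maximizes balanced accuracy with tie-break toward 0.5", {
  expect_equal(select_operating_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)

  scores <- c(0.2, 0.4, 0.6, 0.8); labels <- c(0, 1, 0, 1)
  theta <- select_operating_point(scores, labels)
  bal <- function(th) {
    pred <- scores >= th
    (mean(pred[labels == 1]) + mean(!pred[labels == 0])) / 2
  }
  # exhaustive check over a dense threshold grid
  expect_equal(bal(theta), max(vapply(seq(0, 1, 0.001), bal, numeric(1))))
  expect_equal(bal(theta), 0.75)

  set.seed(13)
  s <- stats::runif(1000); l <- stats::rbinom(1000, 1, 0.5)
  th <- select_operating_point(s, l)
  pred <- s >= th
  expect_lte((mean(pred[l == 1]) + mean(!pred[l == 0])) / 2, 0.6)

  expect_error(select_operating_point(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("NA-zone calibration respects the inconclusive-fraction bound", {
  polarized <- c(rep(0, 50), rep(1, 50))
  labs <- c(rep(0, 50), rep(1, 50))
  zone <- calibrate_na_zone(polarized, labs, 0.5)
  expect_equal(zone, c(0.25, 0.75)) # widest grid width, nothing inside

  set.seed(14)
  scores <- c(stats::runif(5, 0.451, 0.549), stats::runif(47, 0, 0.44), stats::runif(48, 0.56, 1))
  labs2 <- as.numeric(scores > 0.5)
  zone2 <- calibrate_na_zone(scores, labs2, 0.5, max_na_frac = 0.05)
  w2 <- (zone2[2] - zone2[1]) / 2
  expect_gte(w2, 0.05)
  expect_lte(mean(scores > zone2[1] & scores < zone2[2]), 0.05)

  dense <- seq(0.3, 0.7, length.out = 100)
  zone3 <- calibrate_na_zone(dense, as.numeric(dense > 0.5), 0.5, max_na_frac = 0)
  expect_equal(zone3, c(0.5, 0.5))

  # calibration guarantee on arbitrary score sets
  for (i in 1:10) {
    s <- stats::runif(60); l <- stats::rbinom(60, 1, 0.5)
    if (length(unique(l)) < 2) next
    z <- calibrate_na_zone(s, l, 0.5, max_na_frac = 0.05)
    expect_lte(mean(s > z[1] & s < z[2]), 0.05)
  }
})

test_that("classification applies the open NA zone and >= theta boundary", {
  stump <- function(thr, pol, alpha) structure(
    list(feature = "f", threshold = thr, polarity = pol, alpha = alpha),
    class = "decision_stump")
  # two always-disagreeing stumps give every x the score a1 / (a1 + a2)
  const_model <- function(s, theta = 0.5, zone = c(0.45, 0.55)) structure(
    list(stumps = list(stump(-1e9, 1, s), stump(1e9, 1, 1 - s)),
         n_rounds = 2, selected_features = "f",
         operating_threshold = theta, na_zone = zone),
    class = "stump_ensemble")
  X <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  decide <- function(s, ...) classify_measurements(const_model(s, ...), X)$decision

  expect_equal(decide(0.9), "case")
  expect_equal(decide(0.5), "inconclusive")
  expect_equal(decide(0.55), "case")   # zone is open
  expect_equal(decide(0.45), "control")
  # zero-width zone: score exactly at theta is a case
  expect_equal(decide(0.5, zone = c(0.5, 0.5)), "case")

  uncal <- const_model(0.5)
  uncal$operating_threshold <- NA_real_
  expect_error(classify_measurements(uncal, X), "not calibrated")
})

test_that("model JSON round-trip reproduces scores bit-identically", {
  set.seed(15)
  X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- ifelse(X[, 1] > 0, 1, -1)
  fit <- train_adaboost(X, y, n_rounds = 5)
  model <- fit$model
  model$operating_threshold <- 0.5
  model$na_zone <- c(0.45, 0.55)
  path <- tempfile(fileext = ".json")
  model_to_json(model, path)
  restored <- model_from_json(path)
  expect_identical(score_measurements(restored, X), score_measurements(model, X))
})
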