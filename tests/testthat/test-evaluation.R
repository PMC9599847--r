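test_that("grouped k-fold deals subjects evenly and never splits a subject", {
  ids <- sprintf("P%03d", 1:227)
  folds <- grouped_kfold(ids, k = 10, seed = 3)
  sizes <- table(table(folds))
  expect_equal(unname(sizes[["23"]]), 7)
  expect_equal(unname(sizes[["22"]]), 3)

  tiny <- grouped_kfold(sprintf("Q%02d", 1:10), k = 10, seed = 1)
  expect_true(all(table(tiny) == 1))

  meas_ids <- rep(ids, times = sample(1:3, 227, replace = TRUE))
  fold_per_meas <- grouped_kfold(meas_ids, k = 10, seed = 5)[meas_ids]
  expect_true(all(tapply(fold_per_meas, meas_ids, function(f) length(unique(f))) == 1))

  expect_error(grouped_kfold(sprintf("R%d", 1:5), k = 10), "exceeds")
})

test_that("ROC/AUC equals the Mann-Whitney probability and behaves at the extremes", {
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))$auc, 0.75)

  set.seed(16)
  s <- stats::runif(2000); l <- stats::rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_curve(s, l)$auc - 0.5), 0.03)

  for (i in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties on purpose
    l <- stats::rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  s <- stats::rnorm(200); l <- stats::rbinom(200, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_curve(s, l)$auc, ref, tolerance = 1e-10)
})

test_that("confusion counts implement both inconclusive policies", {
  dec <- c(rep("case", 5), rep("control", 5))
  lab <- c(rep(1, 5), rep(0, 5))
  cc <- confusion_counts(dec, lab, "exclude")
  expect_equal(cc$tp + cc$tn, 10)
  expect_equal(cc$fp + cc$fn, 0)

  dec2 <- c("inconclusive", dec); lab2 <- c(1, lab)
  ex <- confusion_counts(dec2, lab2, "exclude")
  expect_equal(ex$n_inconclusive, 1)
  expect_equal(ex$tp, 5); expect_equal(ex$fn, 0)
  ce <- confusion_counts(dec2, lab2, "count_as_error")
  expect_equal(ce$fn, 1)

  dec3 <- c("inconclusive", dec); lab3 <- c(0, lab)
  expect_equal(confusion_counts(dec3, lab3, "count_as_error")$fp, 1)
})

test_that("diagnostic metrics satisfy the likelihood-ratio and Bayes identities", {
  cc <- structure(list(tp = 9, fn = 1, tn = 8, fp = 2, n_inconclusive = 0),
                  class = "confusion_counts")
  m <- diagnostic_metrics(cc)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$plr, 4.5)
  expect_equal(m$plr, m$sensitivity / (1 - m$specificity))
  expect_equal(m$nlr, (1 - m$sensitivity) / m$specificity)

  perfect <- diagnostic_metrics(structure(list(tp = 5, fn = 0, tn = 5, fp = 0,
                                               n_inconclusive = 0),
                                          class = "confusion_counts"))
  expect_equal(perfect$ppv_at_p, 1)
  expect_equal(perfect$npv_at_p, 1)
  expect_equal(perfect$nlr, 0)
  expect_true(is.infinite(perfect$plr))

  # Bayes identity vs direct simulation of a large screened population
  se <- 0.9; sp <- 0.8; p <- 0.32
  m2 <- diagnostic_metrics(cc, prevalence = p)
  set.seed(18)
  n_sim <- 1e6
  disease <- stats::runif(n_sim) < p
  test_pos <- ifelse(disease, stats::runif(n_sim) < se, stats::runif(n_sim) < 1 - sp)
  expect_lt(abs(m2$ppv_at_p - mean(disease[test_pos])), 0.002)
  expect_lt(abs(m2$npv_at_p - mean(!disease[!test_pos])), 0.002)
})

test_that("subject bootstrap gives percentile intervals with correct degenerate behavior", {
  d <- data.frame(subject_id = rep(sprintf("S%02d", 1:20), each = 2), x = 1)
  const <- bootstrap_ci(function(df) mean(df$x), d, n_boot = 100, seed = 1)
  expect_equal(const$lo, 1); expect_equal(const$hi, 1)

  set.seed(19)
  d2 <- data.frame(subject_id = sprintf("S%03d", 1:200),
                   x = stats::rbinom(200, 1, 0.5))
  ci <- bootstrap_ci(function(df) mean(df$x), d2, n_boot = 1000, seed = 2)
  closed_form <- 2 * 1.96 * sqrt(0.5 * 0.5 / 200)
  expect_lt(abs((ci$hi - ci$lo) - closed_form) / closed_form, 0.3)

  again <- bootstrap_ci(function(df) mean(df$x), d2, n_boot = 1000, seed = 2)
  expect_identical(ci, again)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(1, 1, 1, 1)$p_value, 1)
  expect_equal(fisher_exact(3, 1, 1, 3)$p_value, 34 / 70, tolerance = 1e-9)
  expect_equal(fisher_exact(0, 5, 5, 0)$p_value, 2 / 252, tolerance = 1e-9)
  expect_equal(fisher_exact(4, 1, 2, 5)$odds_ratio, 10)
  expect_true(is.infinite(fisher_exact(4, 0, 2, 5)$odds_ratio))

  set.seed(20)
  for (i in 1:40) {
    tab <- as.vector(stats::rmultinom(1, sample(4:12, 1), rep(0.25, 4)))
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if ((a + b) * (c + d) * (a + c) * (b + d) == 0) next
    expect_equal(fisher_exact(a, b, c, d)$p_value,
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-7)
  }
  expect_error(fisher_exact(0, 0, 3, 4), "degenerate")
})

test_that("two-sample KS statistic matches the brute-force ECDF scan", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)

  set.seed(21)
  for (i in 1:30) {
    x <- sample(1:8, sample(3:12, 1), replace = TRUE)
    y <- sample(1:8, sample(3:12, 1), replace = TRUE)
    expect_equal(ks_two_sample(x, y)$statistic, oracle_ks_d(x, y), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("covariate screen flags true associations and stays null otherwise", {
  set.seed(22)
  n <- 200
  correct <- stats::rbinom(n, 1, 0.85) == 1
  cv <- data.frame(measurement_id = seq_len(n), label = rep(c(0, 1), n / 2))
  cv$decision <- ifelse(xor(cv$label == 1, !correct), "case", "control")

  covs <- data.frame(err_copy = !correct, age = stats::rnorm(n, 70, 10),
                     flag = stats::rbinom(n, 1, 0.4) == 1,
                     constant = rep(TRUE, n))
  tab <- covariate_effect_table(cv, covs)
  expect_equal(tab$covariate, sort(tab$covariate))
  expect_lt(tab$p_value[tab$covariate == "err_copy"], 1e-6)
  expect_false(tab$computable[tab$covariate == "constant"])
  expect_gt(tab$p_value[tab$covariate == "age"], 0.001)

  # label-independent covariates give uniform p-values
  many <- as.data.frame(matrix(stats::rnorm(n * 40), n, 40))
  tab2 <- covariate_effect_table(cv, many)
  expect_lte(mean(tab2$p_value < 0.05), 0.10)
})

test_that("grouped CV never leaks a held-out subject into training", {
  set.seed(23)
  n_sub <- 24
  features <- data.frame(
    measurement_id = sprintf("M%02d", 1:n_sub),
    subject_id = sprintf("S%02d", 1:n_sub),
    label = rep(c(TRUE, FALSE), n_sub / 2),
    f1 = stats::rnorm(n_sub), f2 = stats::rnorm(n_sub),
    stringsAsFactors = FALSE
  )
  cfg <- pipeline_config(k = 4, n_rounds = 10, seed = 9)
  base <- cross_validated_scores(features, cfg)

  # duplicating one subject's row only changes training sets of OTHER folds;
  # its own out-of-fold score must be unchanged
  victim <- features$subject_id[1]
  dup <- features[1, ]
  dup$measurement_id <- "M99"
  aug <- rbind(features, dup)
  augd <- cross_validated_scores(aug, cfg)
  expect_equal(augd$score[augd$measurement_id == "M01"],
               base$score[base$measurement_id == "M01"])
  expect_equal(augd$fold[augd$measurement_id == "M99"],
               augd$fold[augd$measurement_id == "M01"])
})
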