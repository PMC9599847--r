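#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value (sum of hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed one)
#' via [stats::fisher.test()], with the sample odds ratio `ad / bc` (0 and
#' `Inf` markers for empty cells) rather than the conditional MLE.
#'
#' @param a,b,c,d Cell counts (`a` = row1/col1, `b` = row1/col2, `c` =
#'   row2/col1, `d` = row2/col2).
#' @return A list: `odds_ratio`, `p_value`.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) stopf("counts must be non-negative integers")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    stopf("degenerate margin: a row or column of the 2x2 table is empty")
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the maximal absolute difference between the two empirical CDFs
#' (exact over the pooled order statistics); the p-value uses the asymptotic
#' Kolmogorov distribution at effective size `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list: `statistic` (D), `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Covariate effect screen on misclassifications
#'
#' Marks each conclusive prediction as correct or misclassified and tests
#' every covariate for association with misclassification: binary covariates
#' by Fisher's exact test on the 2x2 misclassified-by-covariate table,
#' continuous covariates by the two-sample KS test comparing covariate values
#' of misclassified vs correct predictions. No multiple-testing correction is
#' applied. Constant covariates and degenerate tables are reported as
#' not-computable rows.
#'
#' @param cv_scores Output of [cross_validated_scores()] (needs `decision`
#'   and `label`).
#' @param covariates A data.frame of per-measurement covariates, rows aligned
#'   with `cv_scores`.
#' @return A data.frame sorted by covariate name: `covariate`, `test`,
#'   `statistic`, `p_value`, `computable`.
#' @export
covariate_effect_table <- function(cv_scores, covariates) {
  if (nrow(covariates) != nrow(cv_scores)) stopf("covariates must align with cv_scores rows")
  concl <- !is.na(cv_scores$decision) & cv_scores$decision != "inconclusive"
  if (!any(concl)) stopf("no conclusive predictions to analyze")
  y <- to_pm1(cv_scores$label[concl]) == 1
  mis <- (cv_scores$decision[concl] == "case") != y
  cov_c <- covariates[concl, , drop = FALSE]
  rows <- lapply(sort(colnames(cov_c)), function(nm) {
    v <- cov_c[[nm]]
    not_comp <- data.frame(covariate = nm, test = NA_character_,
                           statistic = NA_real_, p_value = NA_real_,
                           computable = FALSE, stringsAsFactors = FALSE)
    if (sum(mis) == 0 || sum(!mis) == 0) return(not_comp)
    if (is.logical(v) || (is.character(v) && length(unique(v)) <= 2) ||
        (is.numeric(v) && all(v %in% c(0, 1)))) {
      lv <- if (is.logical(v)) v else v == sort(unique(v))[length(unique(v))]
      a <- sum(mis & lv); b <- sum(mis & !lv)
      cc <- sum(!mis & lv); dd <- sum(!mis & !lv)
      res <- tryCatch(fisher_exact(a, b, cc, dd), error = function(e) NULL)
      if (is.null(res)) return(not_comp)
      data.frame(covariate = nm, test = "fisher_exact",
                 statistic = res$odds_ratio, p_value = res$p_value,
                 computable = TRUE, stringsAsFactors = FALSE)
    } else {
      if (length(unique(v)) < 2) return(not_comp)
      res <- ks_two_sample(v[mis], v[!mis])
      data.frame(covariate = nm, test = "ks_two_sample",
                 statistic = res$statistic, p_value = res$p_value,
                 computable = TRUE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
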