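# Test-retest reliability of questionnaire items.

#' Test-retest intraclass correlation coefficient
#'
#' Single-measure, absolute-agreement ICC from the two-way mixed-effects
#' decomposition of a subjects-by-administrations table (ICC(A,1)):
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k/n (MSC - MSE))` with `k = 2`
#' administrations, where MSR, MSC and MSE are the subject, administration and
#' residual mean squares.
#'
#' @param score,retest_score Paired numeric vectors; pairs with a missing
#'   value in either administration are dropped.
#' @return The ICC, a number in \[-1, 1\].
#' @export
icc_test_retest <- function(score, retest_score) {
  if (length(score) != length(retest_score)) {
    stop("score and retest_score must have equal length", call. = FALSE)
  }
  ok <- !is.na(score) & !is.na(retest_score)
  x <- cbind(score[ok], retest_score[ok])
  n <- nrow(x)
  k <- 2L
  if (n < 3L) stop("need at least 3 complete test-retest pairs", call. = FALSE)

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total == 0) {
    stop("all scores identical: total variance is zero, ICC undefined",
         call. = FALSE)
  }
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Retain questionnaire items by reproducibility
#'
#' Keeps the items whose test-retest ICC is strictly above the threshold; an
#' ICC exactly at the threshold is dropped.
#'
#' @param icc_by_item Named numeric vector of ICCs (names are item ids), or a
#'   data frame with columns `item_id` and `icc`.
#' @param threshold Retention threshold, default 0.5.
#' @return Character vector of retained item ids.
#' @export
retain_items <- function(icc_by_item, threshold = 0.5) {
  if (is.data.frame(icc_by_item)) {
    icc <- stats::setNames(icc_by_item$icc, icc_by_item$item_id)
  } else {
    icc <- icc_by_item
  }
  if (is.null(names(icc))) stop("ICCs must be named by item", call. = FALSE)
  names(icc)[!is.na(icc) & icc > threshold]
}
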