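#' Root mean squared imputation error
#'
#' The non-normalized RMSE over the imputed block:
#' `sqrt(mean((true - imputed)^2))` across all S x G masked cells.
#'
#' @param true_rows,imputed_rows Matrices of identical shape holding the true
#'   (pre-masking) and imputed values of the masked rows.
#' @return A nonnegative scalar.
#' @export
rmse <- function(true_rows, imputed_rows) {
  if (!identical(dim(as.matrix(true_rows)), dim(as.matrix(imputed_rows)))) {
    stop("true and imputed blocks must have identical shape")
  }
  stopifnot(length(true_rows) >= 1L)
  sqrt(mean((true_rows - imputed_rows)^2))
}

#' DE-calling performance against simulation truth
#'
#' Confusion-matrix summaries of a set of differential-expression calls:
#' `tpr = TP / (TP + FN)` (power), `fpr = FP / (FP + TN)`, and the empirical
#' false discovery proportion `fdr = FP / (TP + FP)`, defined as 0 when no
#' calls are made. A rate whose denominator is empty (e.g. TPR when nothing
#' is truly DE) is reported as `NA`, not 0.
#'
#' @param called Logical vector of features called DE.
#' @param truth Logical vector of true DE status, same length.
#' @return A one-row tibble with columns `tpr`, `fpr`, `fdr`.
#' @export
confusion_metrics <- function(called, truth) {
  stopifnot(length(called) == length(truth))
  called <- as.logical(called)
  truth <- as.logical(truth)
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  fn <- sum(!called & truth)
  tn <- sum(!called & !truth)
  tibble::tibble(
    tpr = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0L) fp / (fp + tn) else NA_real_,
    fdr = if (tp + fp > 0L) fp / (tp + fp) else 0
  )
}
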