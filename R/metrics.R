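# Evaluation metrics for reaction forward prediction.

check_paired <- function(pred, truth) {
  assert_that(length(pred) == length(truth), "argument_error",
              "pred and truth must have equal length (%d vs %d)",
              length(pred), length(truth))
  assert_that(length(pred) > 0L, "argument_error", "empty input")
}

#' Mean absolute error
#'
#' @param pred,truth equal-length numeric vectors (yield fractions).
#' @return mean of `|pred - truth|`.
#' @export
mae <- function(pred, truth) {
  check_paired(pred, truth)
  mean(abs(pred - truth))
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation; degenerate (constant) inputs raise an
#' error instead of returning NaN.
#'
#' @param pred,truth equal-length numeric vectors, length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(pred, truth) {
  check_paired(pred, truth)
  assert_that(length(pred) >= 2L, "argument_error",
              "need at least 2 observations")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop_mf("degenerate_input_error",
            "constant input: Pearson correlation undefined")
  }
  stats::cor(pred, truth, method = "pearson")
}

#' Threshold-based binary classification metrics
#'
#' Both predictions and observations are labelled positive when the (total)
#' yield reaches `threshold`; accuracy and precision of the induced confusion
#' matrix are reported in percent.
#'
#' @param pred_yield,true_yield equal-length numeric yield fractions.
#' @param threshold positive-class yield threshold in \[0, 1\] (default 0.05).
#' @return list with `accuracy` and `precision` (percent; precision is `NA`
#'   with `precision_defined = FALSE` when there are no predicted positives),
#'   and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
binary_metrics <- function(pred_yield, true_yield, threshold = 0.05) {
  check_paired(pred_yield, true_yield)
  assert_that(threshold >= 0 && threshold <= 1, "argument_error",
              "threshold must be in [0, 1]")
  p <- pred_yield >= threshold
  t <- true_yield >= threshold
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  prec_def <- (tp + fp) > 0L
  list(
    accuracy = 100 * (tp + tn) / length(p),
    precision = if (prec_def) 100 * tp / (tp + fp) else NA_real_,
    precision_defined = prec_def,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Aggregate per-fold metrics into a cross-validation report
#'
#' @param per_fold_metrics a data.frame (or named list of equal-length
#'   numeric vectors) with one row/element per fold, e.g. columns `mae`,
#'   `pearson_r`, `accuracy`, `precision`.
#' @return object of class `mf_eval_report`: list with `mean`, `sd` (sample
#'   standard deviation across folds; `NA` with `sd_defined = FALSE` for a
#'   single fold), `n_folds` and the per-fold values.
#' @export
crossval_report <- function(per_fold_metrics) {
  df <- as.data.frame(per_fold_metrics)
  assert_that(nrow(df) >= 1L, "argument_error", "no folds supplied")
  num <- vapply(df, is.numeric, TRUE)
  df <- df[, num, drop = FALSE]
  single <- nrow(df) < 2L
  structure(list(
    mean = vapply(df, mean, 0, na.rm = TRUE),
    sd = if (single) stats::setNames(rep(NA_real_, ncol(df)), names(df))
         else vapply(df, stats::sd, 0, na.rm = TRUE),
    sd_defined = !single,
    n_folds = nrow(df),
    fold_values = df
  ), class = "mf_eval_report")
}

#' @export
print.mf_eval_report <- function(x, ...) {
  cat(sprintf("<mf_eval_report> %d folds\n", x$n_folds))
  for (m in names(x$mean)) {
    cat(sprintf("  %-10s mean %.4f  sd %s\n", m, x$mean[[m]],
                if (x$sd_defined) sprintf("%.4f", x$sd[[m]]) else "NA"))
  }
  invisible(x)
}
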