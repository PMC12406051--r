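#' Classify trials from predicted design variables
#'
#' For indicator-type targets, each trial is assigned the condition whose
#' column of the predicted design-variable matrix has the highest value; ties
#' go to the lowest column index.
#'
#' @param predicted trials x p matrix of predicted indicator values.
#' @return Integer vector of predicted column (condition) indices.
#' @export
classify <- function(predicted) {
  predicted <- as.matrix(predicted)
  max.col(predicted, ties.method = "first")
}

#' Decoding accuracy
#'
#' Proportion of trials whose condition was predicted correctly.
#'
#' @param labels predicted labels.
#' @param truth true labels (same length).
#' @return A proportion in [0, 1].
#' @export
decoding_accuracy <- function(labels, truth) {
  if (length(labels) == 0L || length(truth) == 0L) {
    stop("empty input to decoding_accuracy()", call. = FALSE)
  }
  if (length(labels) != length(truth)) stop("length mismatch", call. = FALSE)
  mean(labels == truth)
}

#' Balanced accuracy
#'
#' Mean of per-class accuracies; insensitive to class imbalance.
#'
#' @inheritParams decoding_accuracy
#' @return A proportion in [0, 1].
#' @export
balanced_accuracy <- function(labels, truth) {
  if (length(labels) == 0L) stop("empty input to balanced_accuracy()", call. = FALSE)
  if (length(labels) != length(truth)) stop("length mismatch", call. = FALSE)
  mean(tapply(labels == truth, truth, mean))
}

#' Predictive correlation
#'
#' Pearson correlation between predicted and actual values of a continuous
#' trial variable, pooled over cross-validation folds.
#'
#' @param predicted numeric vector of predictions.
#' @param actual numeric vector of actual values (non-constant).
#' @return Correlation in [-1, 1]; \code{NaN} with a warning if the actual
#'   values are constant.
#' @export
predictive_correlation <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch", call. = FALSE)
  if (length(actual) < 3L) stop("at least 3 trials are required", call. = FALSE)
  if (stats::sd(actual) == 0) {
    warning("actual values are constant; correlation undefined", call. = FALSE)
    return(NaN)
  }
  stats::cor(predicted, actual)
}

#' Median absolute error
#'
#' Robust error measure for continuous prediction.
#'
#' @inheritParams predictive_correlation
#' @return Median of \code{abs(predicted - actual)}.
#' @export
median_absolute_error <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch", call. = FALSE)
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  stats::median(abs(predicted - actual))
}
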