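#' Cross-validated linear SVM decoding (baseline)
#'
#' Leave-one-session-out decoding with a linear maximum-margin classifier
#' (support vector classification for discrete conditions, epsilon support
#' vector regression for continuous targets), the standard pattern-analysis
#' baseline applied to single-trial amplitude estimates. Features are
#' standardized per voxel using training-fold statistics; the regularization
#' constant is kept at its default (cost = 1).
#'
#' @param estimates a [trial_estimates()] object (>= 2 sessions).
#' @param targets factor/character labels (classification) or numeric vector
#'   (regression), one per trial.
#' @return A list with \code{predicted} (labels or values, in trial order),
#'   \code{actual} and \code{fold}.
#' @export
svm_crossvalidate <- function(estimates, targets) {
  stopifnot(inherits(estimates, "trial_estimates"))
  sess <- unique(estimates$sessions)
  if (length(sess) < 2L) stop("at least 2 sessions are required", call. = FALSE)
  classification <- is.factor(targets) || is.character(targets)
  y <- if (classification) factor(targets) else as.numeric(targets)
  G <- estimates$gamma
  pred <- if (classification) factor(rep(NA, nrow(G)), levels = levels(y))
          else rep(NA_real_, nrow(G))
  for (j in sess) {
    tr <- estimates$sessions != j
    mu <- colMeans(G[tr, , drop = FALSE])
    sd <- apply(G[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    Xtr <- sweep(sweep(G[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(G[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1, scale = FALSE)
    pred[!tr] <- stats::predict(fit, Xte)
  }
  list(predicted = pred, actual = y, fold = estimates$sessions)
}
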