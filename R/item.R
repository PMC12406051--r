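#' Decoding weights of the inverse transformed encoding model
#'
#' Estimates the voxels-by-variables weight matrix W mapping single-trial
#' amplitude estimates to trial-level design variables by generalized least
#' squares with the (calibrated) uncorrelation matrix as trial covariance:
#' \deqn{\hat W = (\hat\Gamma' U^{-1} \hat\Gamma)^{-1} \hat\Gamma' U^{-1} T.}
#'
#' @param gamma trials x voxels matrix of amplitude estimates.
#' @param T trials x p matrix of design variables (indicator and/or
#'   parametric columns).
#' @param U trial covariance (t x t SPD matrix), or \code{NULL} for identity.
#' @param fallback if \code{TRUE}, use the Moore--Penrose pseudoinverse when
#'   \eqn{\hat\Gamma' U^{-1} \hat\Gamma} is singular (e.g. more voxels than
#'   training trials); default \code{FALSE} errors in that regime.
#'
#' @return A v x p weight matrix.
#' @export
item_weights <- function(gamma, T, U = NULL, fallback = FALSE) {
  gamma <- as.matrix(gamma); T <- as.matrix(T)
  if (nrow(gamma) != nrow(T)) stop("'gamma' and 'T' must have one row per trial",
                                   call. = FALSE)
  Gw <- whiten(gamma, U)
  Tw <- whiten(T, U)
  M <- crossprod(Gw)
  rhs <- crossprod(Gw, Tw)
  W <- tryCatch(solve(M, rhs), error = function(e) {
    if (!fallback) {
      stop("Gamma' U^-1 Gamma is singular (", nrow(M), " voxels, ",
           nrow(gamma), " training trials); enable the pseudoinverse ",
           "fallback or reduce the voxel count", call. = FALSE)
    }
    MASS::ginv(M) %*% rhs
  })
  dimnames(W) <- list(colnames(gamma), colnames(T))
  W
}

#' Predict design variables from trial estimates
#'
#' Applies estimated decoding weights to held-out trial estimates:
#' \eqn{\hat T = \hat\Gamma W}.
#'
#' @param W a v x p weight matrix (from [item_weights()]) or a fitted
#'   [item()] model.
#' @param gamma trials x voxels matrix of held-out estimates.
#' @return A trials x p matrix of predicted design variables.
#' @export
predict_design <- function(W, gamma) {
  if (inherits(W, "item")) W <- W$weights_full
  gamma <- as.matrix(gamma)
  if (ncol(gamma) != nrow(W)) {
    stop("voxel mismatch: estimates have ", ncol(gamma),
         " voxels but weights expect ", nrow(W), call. = FALSE)
  }
  gamma %*% W
}

#' Fit an inverse transformed encoding model by cross-validated inversion
#'
#' The central fitting function: decodes trial-level design variables
#' (condition indicators and/or parametric modulators) from single-trial
#' amplitude estimates under leave-one-session-out cross-validation. In each
#' fold, the trial covariance of the training sessions is taken from the
#' analytically derived uncorrelation matrices (optionally re-calibrated by
#' [reml_calibrate()] into a mixture of white trial variability and
#' design-induced covariance), decoding weights are estimated by generalized
#' least squares, and the held-out session's design variables are predicted.
#' Predictions are concatenated over folds in trial order and scored once.
#'
#' @param estimates a [trial_estimates()] object spanning at least two
#'   sessions, with uncorrelation matrices attached.
#' @param targets the design variables to decode: a factor/character vector
#'   of per-trial condition labels (classification), a numeric vector
#'   (regression), or a trials x p matrix such as one built by
#'   [build_transformation_matrix()].
#' @param calibrate recalibrate the trial covariance by ReML per training
#'   fold (default \code{TRUE}).
#' @param intercept append a constant column to the estimates (default
#'   \code{FALSE}).
#' @param fallback \code{"error"} (default) or \code{"pseudoinverse"} for
#'   singular training systems (more voxels than training trials).
#'
#' @return An object of class \code{"item"} with elements \code{predicted}
#'   (trials x p, cross-validated), \code{actual}, \code{fold} (held-out
#'   session per trial), \code{weights} (per-fold), \code{weights_full}
#'   (fit on all sessions, used by \code{predict}), \code{task}, and
#'   \code{reml} (per-fold variance weights, if calibrated). Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}.
#'
#' @seealso [item_weights()], [predict_design()], [decoding_accuracy()],
#'   [predictive_correlation()]
#' @export
item <- function(estimates, targets, calibrate = TRUE, intercept = FALSE,
                 fallback = c("error", "pseudoinverse")) {
  stopifnot(inherits(estimates, "trial_estimates"))
  fallback <- match.arg(fallback)
  use_pinv <- fallback == "pseudoinverse"
  sess <- unique(estimates$sessions)
  if (length(sess) < 2L) {
    stop("leave-one-session-out cross-validation requires at least 2 sessions",
         call. = FALSE)
  }
  tt <- parse_targets(targets, nrow(estimates$gamma))
  Tm <- tt$T
  gamma <- estimates$gamma
  if (intercept) gamma <- cbind(gamma, `(intercept)` = 1)

  predicted <- matrix(NA_real_, nrow(Tm), ncol(Tm),
                      dimnames = list(NULL, colnames(Tm)))
  weights <- vector("list", length(sess))
  names(weights) <- sess
  reml_w <- list()

  fit_fold <- function(train_sess) {
    idx <- estimates$sessions %in% train_sess
    est_tr <- trial_estimates(estimates$gamma[idx, , drop = FALSE],
                              estimates$sessions[idx],
                              U = estimates$U[train_sess],
                              method = estimates$method)
    T_tr <- Tm[idx, , drop = FALSE]
    if (calibrate) {
      fit <- reml_calibrate(est_tr, T = T_tr)
      U_tr <- block_diag(fit$calibrated_blocks)
      lam <- fit$variance_weights
    } else {
      U_tr <- block_diag(estimates$U[train_sess])
      lam <- NULL
    }
    g_tr <- gamma[idx, , drop = FALSE]
    list(W = item_weights(g_tr, T_tr, U_tr, fallback = use_pinv), lambda = lam)
  }

  for (j in sess) {
    f <- fit_fold(setdiff(sess, j))
    weights[[j]] <- f$W
    if (!is.null(f$lambda)) reml_w[[j]] <- f$lambda
    test <- estimates$sessions == j
    predicted[test, ] <- gamma[test, , drop = FALSE] %*% f$W
  }
  full <- fit_fold(sess)

  structure(list(predicted = predicted, actual = Tm,
                 fold = estimates$sessions,
                 weights = weights, weights_full = full$W,
                 task = tt$task, levels = tt$levels,
                 calibrate = calibrate, intercept = intercept,
                 reml = reml_w, method = estimates$method,
                 call = match.call()),
            class = "item")
}

parse_targets <- function(targets, n_trials) {
  if (is.factor(targets) || is.character(targets)) {
    f <- factor(targets)
    if (length(f) != n_trials) stop("'targets' must have one entry per trial",
                                    call. = FALSE)
    Tm <- stats::model.matrix(~ f - 1)
    colnames(Tm) <- levels(f)
    attr(Tm, "assign") <- NULL; attr(Tm, "contrasts") <- NULL
    return(list(T = Tm, task = "classification", levels = levels(f)))
  }
  Tm <- as.matrix(targets)
  if (nrow(Tm) != n_trials) stop("'targets' must have one row per trial",
                                 call. = FALSE)
  kind <- attr(targets, "column_kind")
  task <- if (!is.null(kind) && all(kind == "indicator")) "classification"
          else if (is.null(kind) && all(Tm %in% c(0, 1)) && ncol(Tm) > 1 &&
                   all(rowSums(Tm) == 1)) "classification"
          else "regression"
  if (is.null(colnames(Tm))) colnames(Tm) <- paste0("target_", seq_len(ncol(Tm)))
  list(T = Tm, task = task,
       levels = if (task == "classification") colnames(Tm) else NULL)
}

#' @export
print.item <- function(x, ...) {
  cat("Inverse transformed encoding model (cross-validated)\n")
  cat(sprintf("  %d trials, %d sessions/folds, %d voxels, estimator %s\n",
              nrow(x$predicted), length(x$weights),
              nrow(x$weights_full) - x$intercept, x$method))
  if (x$task == "classification") {
    cat(sprintf("  task: classification (%d classes), decoding accuracy %.3f\n",
                length(x$levels), decoding_accuracy(classify(x$predicted),
                                                    true_labels(x))))
  } else {
    cc <- vapply(seq_len(ncol(x$predicted)), function(k) {
      suppressWarnings(predictive_correlation(x$predicted[, k], x$actual[, k]))
    }, numeric(1))
    cat(sprintf("  task: regression (%d target%s), mean predictive correlation %.3f\n",
                ncol(x$predicted), if (ncol(x$predicted) > 1) "s" else "",
                mean(cc, na.rm = TRUE)))
  }
  invisible(x)
}

true_labels <- function(x) max.col(x$actual, ties.method = "first")

#' @export
summary.item <- function(object, ...) {
  folds <- unique(object$fold)
  if (object$task == "classification") {
    truth <- true_labels(object)
    lab <- classify(object$predicted)
    per_fold <- vapply(folds, function(j) {
      sel <- object$fold == j
      decoding_accuracy(lab[sel], truth[sel])
    }, numeric(1))
    out <- list(task = "classification",
                pooled = c(accuracy = decoding_accuracy(lab, truth),
                           balanced_accuracy = balanced_accuracy(lab, truth)),
                per_fold = stats::setNames(per_fold, folds))
  } else {
    cols <- colnames(object$predicted)
    pooled <- t(vapply(seq_along(cols), function(k) {
      c(correlation = suppressWarnings(
          predictive_correlation(object$predicted[, k], object$actual[, k])),
        mae = median_absolute_error(object$predicted[, k], object$actual[, k]))
    }, numeric(2)))
    rownames(pooled) <- cols
    per_fold <- vapply(folds, function(j) {
      sel <- object$fold == j
      mean(vapply(seq_along(cols), function(k) {
        suppressWarnings(predictive_correlation(object$predicted[sel, k],
                                                object$actual[sel, k]))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    out <- list(task = "regression", pooled = pooled,
                per_fold = stats::setNames(per_fold, folds))
  }
  class(out) <- "summary.item"
  out
}

#' @export
print.summary.item <- function(x, ...) {
  cat("Cross-validated decoding performance (", x$task, ")\n", sep = "")
  cat("Pooled:\n")
  print(round(x$pooled, 4))
  cat("Per fold (held-out session):\n")
  print(round(x$per_fold, 4))
  invisible(x)
}

#' @export
coef.item <- function(object, fold = NULL, ...) {
  if (is.null(fold)) object$weights_full else object$weights[[as.character(fold)]]
}

#' @export
predict.item <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "trial_estimates")) newdata <- newdata$gamma
  newdata <- as.matrix(newdata)
  if (object$intercept) newdata <- cbind(newdata, 1)
  pred <- predict_design(object$weights_full, newdata)
  if (type == "class") {
    if (object$task != "classification") {
      stop("type = 'class' is only available for classification models", call. = FALSE)
    }
    return(factor(object$levels[classify(pred)], levels = object$levels))
  }
  pred
}

#' @export
fitted.item <- function(object, ...) object$predicted

#' @export
residuals.item <- function(object, ...) object$actual - object$predicted

#' @export
plot.item <- function(x, column = 1L, ...) {
  if (x$task == "regression") {
    graphics::plot(x$actual[, column], x$predicted[, column],
                   xlab = "actual", ylab = "predicted (cross-validated)",
                   main = colnames(x$predicted)[column], ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    cls <- factor(x$levels[true_labels(x)], levels = x$levels)
    graphics::boxplot(x$predicted[, column] ~ cls,
                      xlab = "true condition",
                      ylab = paste0("predicted value of '",
                                    colnames(x$predicted)[column], "'"), ...)
  }
  invisible(x)
}
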