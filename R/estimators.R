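#' Construct a trial-estimates container
#'
#' Holds a trials-by-voxels matrix of estimated single-trial response
#' amplitudes together with the session label of every trial and, per session,
#' the trial-by-trial "uncorrelation" matrix \eqn{U = (X_t' V^{-1} X_t)^{-1}}
#' describing the covariance that the overlapping HRF regressors induce
#' between the estimates.
#'
#' @param gamma numeric matrix, trials x voxels.
#' @param sessions vector of session ids, one per row of \code{gamma}; rows
#'   must be grouped by session.
#' @param U named list of per-session t x t uncorrelation matrices (names =
#'   session ids), or \code{NULL}.
#' @param method one of \code{"LSA"}, \code{"LSS"}, \code{"FRACRIDGE"}.
#' @return An object of class \code{"trial_estimates"}.
#' @export
trial_estimates <- function(gamma, sessions, U = NULL, method = "LSA") {
  gamma <- as.matrix(gamma)
  sessions <- as.character(sessions)
  if (length(sessions) != nrow(gamma)) {
    stop("'sessions' must have one entry per trial", call. = FALSE)
  }
  if (anyDuplicated(rle(sessions)$values)) {
    stop("rows of 'gamma' must be grouped by session", call. = FALSE)
  }
  if (!is.null(U)) {
    tab <- table(factor(sessions, levels = unique(sessions)))
    if (!all(names(tab) %in% names(U))) {
      stop("'U' must be a named list covering every session", call. = FALSE)
    }
    for (s in names(tab)) {
      if (!all(dim(U[[s]]) == tab[[s]])) {
        stop("U block for session ", s, " has wrong dimension", call. = FALSE)
      }
    }
  }
  structure(list(gamma = gamma, sessions = sessions, U = U,
                 method = match.arg(method, c("LSA", "LSS", "FRACRIDGE"))),
            class = "trial_estimates")
}

#' @export
print.trial_estimates <- function(x, ...) {
  cat(sprintf("Trial-wise response estimates (%s): %d trials x %d voxels, %d session(s)\n",
              x$method, nrow(x$gamma), ncol(x$gamma), length(unique(x$sessions))))
  invisible(x)
}

#' Combine per-session trial estimates
#'
#' Stacks \code{trial_estimates} from several sessions (rows concatenated in
#' the order given, uncorrelation matrices kept block-wise per session).
#'
#' @param ... \code{trial_estimates} objects, or a single list of them.
#' @return A single \code{trial_estimates} object.
#' @export
combine_trial_estimates <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "trial_estimates")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  method <- unique(vapply(xs, function(x) x$method, character(1)))
  if (length(method) != 1L) stop("cannot combine estimates from different methods", call. = FALSE)
  gamma <- do.call(rbind, lapply(xs, function(x) x$gamma))
  sessions <- unlist(lapply(xs, function(x) x$sessions), use.names = FALSE)
  Us <- do.call(c, lapply(xs, function(x) x$U))
  trial_estimates(gamma, sessions, U = Us, method = method)
}

# whiten rows of M by the scan covariance V (identity if NULL): returns R^-T M
# where V = R'R (Cholesky), so that crossprod(whiten(X), whiten(Y)) = X'V^-1 Y.
whiten <- function(M, V) {
  if (is.null(V)) return(M)
  R <- chol(V)
  forwardsolve(t(R), M)
}

check_design_rank <- function(Xw, what = "design matrix", threshold = 1e8) {
  d <- svd(Xw, nu = 0, nv = 0)$d
  if (min(d) <= 0 || max(d) / min(d) > threshold) {
    qrX <- qr(Xw)
    bad <- if (qrX$rank < ncol(Xw)) {
      cols <- colnames(Xw)
      if (is.null(cols)) cols <- paste0("col", seq_len(ncol(Xw)))
      paste0("; collinear column(s): ",
             paste(cols[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xw))]], collapse = ", "))
    } else ""
    stop(sprintf("%s is (near-)singular: condition number %.3g exceeds %g%s",
                 what, max(d) / min(d), threshold, bad), call. = FALSE)
  }
  invisible(TRUE)
}

#' Trial-wise amplitude estimation by joint weighted least squares (LS-A)
#'
#' Estimates all single-trial response amplitudes jointly from one session's
#' data by (generalized) least squares,
#' \eqn{\hat\Gamma = (X_t' V^{-1} X_t)^{-1} X_t' V^{-1} Y}. Nuisance-column
#' coefficients are estimated in the same fit but excluded from the returned
#' amplitude matrix.
#'
#' @param signal numeric matrix, scans x voxels.
#' @param design a [build_trialwise_design()] object for the same session.
#' @return A [trial_estimates()] object (method \code{"LSA"}) with the
#'   session's uncorrelation matrix attached.
#' @export
lsa_estimate <- function(signal, design) {
  signal <- as.matrix(signal)
  stopifnot(inherits(design, "trialwise_design"))
  if (nrow(signal) != design$n_scans) {
    stop("'signal' must have one row per scan", call. = FALSE)
  }
  X <- design$matrix
  V <- design$scan_cov
  Xw <- whiten(X, V)
  Yw <- whiten(signal, V)
  check_design_rank(Xw)
  beta <- qr.coef(qr(Xw), Yw)
  gamma <- beta[design$trial_cols, , drop = FALSE]
  dimnames(gamma) <- NULL
  s <- design_session(design)
  U <- stats::setNames(list(uncorrelation_matrix(design)), s)
  trial_estimates(gamma, rep(s, length(design$trial_cols)), U = U, method = "LSA")
}

design_session <- function(design) {
  s <- unique(design$trial_info$session)
  if (length(s) != 1L) "1" else as.character(s)
}

#' Trial-wise amplitude estimation by separate per-trial models (LS-S)
#'
#' Estimates each trial's response amplitude from its own GLM containing one
#' regressor for that trial, one regressor summing all other trials, and the
#' design's nuisance regressors; the trial's estimate is the coefficient of
#' its own regressor. One model is fitted per trial.
#'
#' @inheritParams lsa_estimate
#' @return A [trial_estimates()] object (method \code{"LSS"}). The number of
#'   per-trial model fits performed is attached as attribute \code{"n_fits"}.
#' @export
lss_estimate <- function(signal, design) {
  signal <- as.matrix(signal)
  stopifnot(inherits(design, "trialwise_design"))
  if (nrow(signal) != design$n_scans) {
    stop("'signal' must have one row per scan", call. = FALSE)
  }
  tc <- design$trial_cols
  t <- length(tc)
  if (t < 2L) {
    stop("LS-S requires at least 2 trials (the all-other-trials regressor ",
         "would be empty); use lsa_estimate() instead", call. = FALSE)
  }
  nc <- design$nuisance_cols
  q <- length(nc)
  V <- design$scan_cov
  Xw <- whiten(design$matrix, V)
  Yw <- whiten(signal, V)
  check_design_rank(Xw)

  # all per-trial normal equations assembled from one set of cross-products
  G <- crossprod(Xw)
  XtY <- crossprod(Xw, Yw)
  g <- G[tc, tc, drop = FALSE]
  rs <- rowSums(g)
  S2 <- sum(g)
  GN <- G[tc, nc, drop = FALSE]
  colsGN <- colSums(GN)
  NN <- G[nc, nc, drop = FALSE]
  ty <- XtY[tc, , drop = FALSE]
  sum_ty <- colSums(ty)
  Ny <- XtY[nc, , drop = FALSE]

  v <- ncol(signal)
  gamma <- matrix(NA_real_, t, v)
  for (i in seq_len(t)) {
    M <- matrix(0, 2L + q, 2L + q)
    M[1, 1] <- g[i, i]
    M[1, 2] <- M[2, 1] <- rs[i] - g[i, i]
    M[2, 2] <- S2 - 2 * rs[i] + g[i, i]
    if (q) {
      M[1, 2 + seq_len(q)] <- GN[i, ]
      M[2 + seq_len(q), 1] <- GN[i, ]
      M[2, 2 + seq_len(q)] <- colsGN - GN[i, ]
      M[2 + seq_len(q), 2] <- colsGN - GN[i, ]
      M[2 + seq_len(q), 2 + seq_len(q)] <- NN
    }
    rhs <- rbind(ty[i, ], sum_ty - ty[i, ], Ny)
    coefs <- tryCatch(solve(M, rhs), error = function(e) {
      stop("singular per-trial design in LS-S fit for trial ", i, call. = FALSE)
    })
    gamma[i, ] <- coefs[1, ]
  }
  s <- design_session(design)
  U <- stats::setNames(list(uncorrelation_matrix(design)), s)
  out <- trial_estimates(gamma, rep(s, t), U = U, method = "LSS")
  attr(out, "n_fits") <- t
  out
}

#' Trial-by-trial uncorrelation matrix
#'
#' Computes \eqn{U}, the trial block of \eqn{(X' V^{-1} X)^{-1}} for the full
#' design (trial plus nuisance columns), i.e. the covariance structure that
#' joint least-squares estimation induces between single-trial amplitude
#' estimates. With closely spaced trials the overlapping HRF regressors make
#' adjacent-trial entries of \eqn{U} large and negative; with long
#' inter-stimulus intervals \eqn{U} approaches a diagonal matrix. Including
#' the nuisance columns in the inverse accounts for covariation between
#' trial-evoked and nuisance-related signal.
#'
#' @inheritParams lsa_estimate
#' @return A symmetric positive-definite t x t matrix.
#' @export
uncorrelation_matrix <- function(design) {
  stopifnot(inherits(design, "trialwise_design"))
  Xw <- whiten(design$matrix, design$scan_cov)
  check_design_rank(Xw)
  XtX <- crossprod(Xw)
  inv <- tryCatch(chol2inv(chol(XtX)), error = function(e) {
    stop("singular regressor cross-product; cannot form uncorrelation matrix",
         call. = FALSE)
  })
  U <- inv[design$trial_cols, design$trial_cols, drop = FALSE]
  (U + t(U)) / 2
}

#' Programmatic trial-wise design construction
#'
#' Low-level constructor wrapping an existing design matrix (e.g. for toy
#' examples or externally built designs) in the container that the estimators
#' expect.
#'
#' @param matrix scans x regressors design matrix.
#' @param trial_cols indices of the trial regressors.
#' @param nuisance_cols indices of the remaining regressors (default: all
#'   others).
#' @param TR repetition time in seconds.
#' @param scan_cov optional scan covariance V.
#' @param session session id (default 1).
#' @return A \code{"trialwise_design"} object.
#' @export
trialwise_design <- function(matrix, trial_cols,
                             nuisance_cols = setdiff(seq_len(ncol(matrix)), trial_cols),
                             TR = 1, scan_cov = NULL, session = 1L) {
  matrix <- as.matrix(matrix)
  trial_cols <- as.integer(trial_cols)
  nuisance_cols <- as.integer(nuisance_cols)
  if (length(intersect(trial_cols, nuisance_cols))) {
    stop("trial and nuisance columns must be disjoint", call. = FALSE)
  }
  if (!is.null(scan_cov)) check_scan_cov(scan_cov, nrow(matrix))
  structure(list(matrix = matrix, trial_cols = trial_cols,
                 nuisance_cols = nuisance_cols, TR = TR,
                 n_scans = nrow(matrix), oversampling = NA_integer_,
                 scan_cov = scan_cov,
                 trial_info = data.frame(session = rep(as.integer(session),
                                                       length(trial_cols)))),
            class = "trialwise_design")
}
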