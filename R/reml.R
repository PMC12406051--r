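#' Restricted maximum likelihood calibration of the trial covariance
#'
#' Single-trial amplitude estimates carry two sources of trial-level
#' (co)variance: natural trial-to-trial variability of the underlying
#' responses (white, proportional to the identity) and estimation covariance
#' induced by overlapping HRF regressors (proportional to the uncorrelation
#' matrix U). This function separates the two by fitting
#' \deqn{Cov = \lambda_1 I + \lambda_2 U}
#' to the voxel-pooled second moment of the estimate rows by restricted
#' maximum likelihood (voxels as replicates, the trial-level design T as the
#' mean structure), using Fisher scoring on the restricted log-likelihood in
#' log-parameter space with step halving.
#'
#' @param estimates a [trial_estimates()] object with uncorrelation matrices
#'   attached (at least 2 voxels).
#' @param T optional trial-level design matrix (t x p) giving the mean
#'   structure to be restricted out; default a constant column.
#' @param max_iter maximum Fisher-scoring iterations (default 32).
#' @param tol convergence tolerance on the relative change of the restricted
#'   log-likelihood (default 1e-6).
#'
#' @return An object of class \code{"reml_fit"}: list with
#'   \code{variance_weights} (\eqn{\lambda_1, \lambda_2}),
#'   \code{calibrated_cov} (the fitted t x t covariance),
#'   \code{calibrated_blocks} (per-session \eqn{\lambda_1 I + \lambda_2 U_s}),
#'   \code{log_likelihood_trace} and \code{converged}.
#' @export
reml_calibrate <- function(estimates, T = NULL, max_iter = 32L, tol = 1e-6) {
  stopifnot(inherits(estimates, "trial_estimates"))
  G <- estimates$gamma
  t_tot <- nrow(G)
  v <- ncol(G)
  if (v < 2L) stop("ReML calibration needs at least 2 voxels", call. = FALSE)
  if (is.null(estimates$U)) stop("estimates carry no uncorrelation matrices", call. = FALSE)
  sess <- unique(estimates$sessions)
  U <- block_diag(estimates$U[sess])
  X <- if (is.null(T)) matrix(1, t_tot, 1) else as.matrix(T)
  if (nrow(X) != t_tot) stop("'T' must have one row per trial", call. = FALSE)

  S <- tcrossprod(G) / v
  I_t <- diag(t_tot)

  rell <- function(lam) {
    C <- lam[1] * I_t + lam[2] * U
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Ci <- chol2inv(R)
    CiX <- Ci %*% X
    A <- solve(crossprod(X, CiX))
    P <- Ci - CiX %*% A %*% t(CiX)
    F <- -v / 2 * (2 * sum(log(diag(R))) + determinant(crossprod(X, CiX))$modulus[1] +
                     sum(P * S))
    list(F = as.numeric(F), P = P)
  }

  # scale-aware initialization: split the average estimate variance evenly
  s0 <- max(sum(diag(S)) / t_tot, .Machine$double.eps)
  uscale <- sum(diag(U)) / t_tot
  lam <- c(0.5 * s0, 0.5 * s0 / uscale)
  h <- log(lam)
  cur <- rell(exp(h))
  trace <- cur$F
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    P <- cur$P
    PQ1 <- P
    PQ2 <- P %*% U
    PS <- P %*% S
    g <- v / 2 * c(sum(PQ1 * t(PS)) - sum(diag(PQ1)),
                   sum(PQ2 * t(PS)) - sum(diag(PQ2)))
    H <- matrix(0, 2, 2)
    H[1, 1] <- v / 2 * sum(PQ1 * t(PQ1))
    H[1, 2] <- H[2, 1] <- v / 2 * sum(PQ1 * t(PQ2))
    H[2, 2] <- v / 2 * sum(PQ2 * t(PQ2))
    lam <- exp(h)
    gh <- lam * g
    Hh <- (lam %o% lam) * H
    Hh <- Hh + diag(2) * (1e-8 * max(diag(Hh), .Machine$double.eps))
    dh <- tryCatch(solve(Hh, gh), error = function(e) gh / max(diag(Hh)))
    dh <- pmax(pmin(dh, 4), -4)

    # step-halving so the restricted log-likelihood never decreases
    step <- 1
    repeat {
      h_new <- pmax(h + step * dh, log(s0) - 32)
      nxt <- rell(exp(h_new))
      if (!is.null(nxt) && nxt$F >= cur$F - 1e-10 * abs(cur$F)) break
      step <- step / 2
      if (step < 1 / 64) { nxt <- cur; h_new <- h; break }
    }
    dF <- abs(nxt$F - cur$F)
    h <- h_new
    cur <- nxt
    trace <- c(trace, cur$F)
    if (dF <= tol * max(1, abs(cur$F))) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("ReML calibration did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  lam <- exp(h)
  blocks <- lapply(estimates$U[sess], function(Us) {
    lam[1] * diag(nrow(Us)) + lam[2] * Us
  })
  structure(list(variance_weights = stats::setNames(lam, c("identity", "uncorrelation")),
                 calibrated_cov = lam[1] * I_t + lam[2] * U,
                 calibrated_blocks = blocks,
                 log_likelihood_trace = trace,
                 converged = converged),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("ReML variance-component fit (Cov = l1*I + l2*U)\n")
  cat(sprintf("  l1 (natural trial variability) = %.4g\n", x$variance_weights[1]))
  cat(sprintf("  l2 (design-induced covariance) = %.4g\n", x$variance_weights[2]))
  cat(sprintf("  converged: %s after %d iterations\n", x$converged,
              length(x$log_likelihood_trace) - 1L))
  invisible(x)
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  M <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    M[idx, idx] <- b
    at <- at + nrow(b)
  }
  M
}
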