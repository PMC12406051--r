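#' Fractional ridge regression
#'
#' Solves ridge regression reparameterized by the "fraction": the ratio of
#' the L2 norm of the regularized coefficient vector to the norm of the
#' unregularized (ordinary least squares) solution. For each response column
#' and each requested fraction, the corresponding ridge penalty is found by
#' monotone interpolation of the norm-ratio curve evaluated on a dense
#' logarithmic penalty grid, and coefficients are computed at that penalty
#' via the singular value decomposition of the design.
#'
#' @param X design matrix (n x t), full column rank.
#' @param Y response matrix (n x v).
#' @param fractions numeric vector of target fractions in (0, 1].
#' @param grid_size number of log-spaced penalties in the interpolation grid.
#'
#' @return A list with \code{coef} (array t x v x length(fractions)),
#'   \code{alpha} (matrix length(fractions) x v of selected penalties) and
#'   \code{fractions}.
#' @export
fracridge <- function(X, Y, fractions, grid_size = 161L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  sv <- svd(X)
  d <- sv$d
  if (min(d) <= max(d) * 1e-12) stop("design matrix is rank deficient", call. = FALSE)
  cc <- crossprod(sv$u, Y)                    # rotated OLS coordinates, t x v
  v <- ncol(Y); t <- ncol(X); nf <- length(fractions)

  d2 <- d^2
  log_alpha <- seq(log10(min(d2)) - 6, log10(max(d2)) + 8, length.out = grid_size)
  alphas <- 10^log_alpha
  ols_norm2 <- colSums((cc / d)^2)            # per-voxel ||b_OLS||^2

  # fraction curve f(alpha) per voxel on the grid (decreasing in alpha)
  frac_grid <- matrix(NA_real_, grid_size, v)
  for (k in seq_len(grid_size)) {
    s <- d / (d2 + alphas[k])
    frac_grid[k, ] <- sqrt(colSums((s * cc)^2) / ols_norm2)
  }

  alpha_sel <- matrix(0, nf, v)
  for (j in seq_len(v)) {
    if (ols_norm2[j] <= 0) { alpha_sel[, j] <- 0; next }
    xs <- rev(frac_grid[, j])                 # increasing in fraction
    ys <- rev(log_alpha)
    keep <- !duplicated(xs)
    xs <- xs[keep]; ys <- ys[keep]
    if (max(xs) < 1) { xs <- c(xs, 1); ys <- c(ys, log_alpha[1] - 6) }
    la <- stats::approx(xs, ys, xout = fractions, rule = 2)$y
    a <- 10^la
    a[fractions >= 1] <- 0                    # fraction 1 = no regularization
    alpha_sel[, j] <- a
  }

  coefs <- array(NA_real_, dim = c(t, v, nf))
  for (k in seq_len(nf)) {
    S <- d / outer(d2, alpha_sel[k, ], `+`)   # t x v shrinkage factors
    coefs[, , k] <- sv$v %*% (S * cc)
  }
  list(coef = coefs, alpha = alpha_sel, fractions = fractions)
}

#' Trial-wise amplitude estimation by fractional ridge regression
#'
#' Baseline single-trial estimator in the spirit of GLMsingle reduced to its
#' fractional-ridge component: nuisance regressors are projected out of the
#' trial regressors and the data, per-voxel ridge solutions are computed over
#' a grid of fractions, and each voxel's fraction is selected by
#' leave-one-session-out cross-validated prediction accuracy of the held-out
#' session's time series (the held-out session's trial amplitudes set to the
#' voxel's mean training-session estimate). Requires at least two sessions
#' unless a single fixed fraction is given.
#'
#' @param signal a scans x voxels matrix, or a list of them (one per session).
#' @param design a [build_trialwise_design()], or a list of them matching
#'   \code{signal}.
#' @param fractions candidate fractions (default 0.05 to 1 in steps of 0.05).
#' @return A [trial_estimates()] object (method \code{"FRACRIDGE"}) with the
#'   per-voxel selected fractions attached as attribute \code{"fraction"}.
#' @export
fracridge_estimate <- function(signal, design,
                               fractions = seq(0.05, 1, by = 0.05)) {
  if (!is.list(signal) || is.matrix(signal)) signal <- list(signal)
  if (inherits(design, "trialwise_design")) design <- list(design)
  if (length(signal) != length(design)) {
    stop("'signal' and 'design' must have one element per session", call. = FALSE)
  }
  if (!length(fractions)) stop("at least one fraction is required", call. = FALSE)
  S <- length(signal)
  if (S < 2L && length(fractions) > 1L) {
    stop("cross-validated fraction selection requires at least 2 sessions; ",
         "supply a single fixed fraction for single-session estimation",
         call. = FALSE)
  }

  prep <- lapply(seq_len(S), function(s) {
    des <- design[[s]]
    Y <- as.matrix(signal[[s]])
    if (nrow(Y) != des$n_scans) stop("signal/design scan mismatch in session ", s,
                                     call. = FALSE)
    Xw <- whiten(des$matrix, des$scan_cov)
    Yw <- whiten(Y, des$scan_cov)
    Xt <- Xw[, des$trial_cols, drop = FALSE]
    if (length(des$nuisance_cols)) {
      N <- Xw[, des$nuisance_cols, drop = FALSE]
      qn <- qr(N)
      Xt <- Xt - qr.fitted(qn, Xt)
      Yw <- Yw - qr.fitted(qn, Yw)
    }
    fr <- fracridge(Xt, Yw, fractions)
    list(Xt = Xt, Y = Yw, fr = fr, des = des)
  })

  v <- ncol(prep[[1]]$Y)
  nf <- length(fractions)
  if (nf > 1L) {
    # per-voxel cross-validated R^2 of held-out time-series prediction
    score <- matrix(0, nf, v)
    for (s in seq_len(S)) {
      xsum <- rowSums(prep[[s]]$Xt)
      ss_tot <- colSums(prep[[s]]$Y^2)
      ss_tot[ss_tot <= 0] <- Inf
      for (k in seq_len(nf)) {
        mb <- Reduce(`+`, lapply(setdiff(seq_len(S), s), function(r) {
          colMeans(matrix(prep[[r]]$fr$coef[, , k], ncol = v))
        })) / (S - 1)
        resid <- prep[[s]]$Y - outer(xsum, mb)
        score[k, ] <- score[k, ] + (1 - colSums(resid^2) / ss_tot)
      }
    }
    best <- apply(score, 2, which.max)
  } else {
    best <- rep(1L, v)
  }

  ests <- lapply(seq_len(S), function(s) {
    co <- prep[[s]]$fr$coef
    gamma <- matrix(NA_real_, dim(co)[1], v)
    for (j in seq_len(v)) gamma[, j] <- co[, j, best[j]]
    des <- prep[[s]]$des
    ses <- design_session(des)
    U <- stats::setNames(list(uncorrelation_matrix(des)), ses)
    trial_estimates(gamma, rep(ses, nrow(gamma)), U = U, method = "FRACRIDGE")
  })
  out <- combine_trial_estimates(ests)
  attr(out, "fraction") <- fractions[best]
  out
}
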