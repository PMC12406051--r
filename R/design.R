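#' Build an HRF-convolved trial-wise design matrix
#'
#' Constructs the scan-by-regressor design matrix of the trial-wise GLM: one
#' HRF onset regressor per trial-wise event, plus one pooled condition
#' regressor per non-trial-wise ("nuisance") condition, an optional discrete
#' cosine high-pass filter set and an optional constant. Each regressor is
#' built by placing a boxcar of the event's duration at its onset on a
#' microtime grid of resolution \code{TR/oversampling} (onsets need not be
#' scan-locked), convolving with the HRF kernel and sampling at the middle of
#' every scan acquisition interval. Convolution is scaled by the grid spacing,
#' so a regressor approximates the continuous integral of the stimulus boxcar
#' against the peak-normalized HRF.
#'
#' @param events an [event_table()] holding a single session.
#' @param n_scans number of volumes acquired.
#' @param TR repetition time in seconds.
#' @param hrf HRF kernel sampled at \code{TR/oversampling}; default
#'   [canonical_hrf()] at that resolution.
#' @param oversampling microtime bins per TR (default 16).
#' @param constant append a constant regressor (default \code{TRUE}).
#' @param hpf_cutoff optional high-pass filter cutoff in seconds; adds a
#'   discrete cosine basis for drifts slower than the cutoff.
#' @param scan_cov optional \code{n_scans x n_scans} symmetric
#'   positive-definite scan covariance matrix V (default \code{NULL} =
#'   identity; see [ar1_scan_cov()]).
#'
#' @return An object of class \code{"trialwise_design"}: a list with elements
#'   \code{matrix} (\code{n_scans x n_columns}), \code{trial_cols},
#'   \code{nuisance_cols}, \code{TR}, \code{n_scans}, \code{scan_cov} and
#'   \code{trial_info} (the trial-wise events, in column order).
#'
#' @export
build_trialwise_design <- function(events, n_scans, TR, hrf = NULL,
                                   oversampling = 16L, constant = TRUE,
                                   hpf_cutoff = NULL, scan_cov = NULL) {
  validate_event_table(events)
  if (length(unique(events$session)) != 1L) {
    stop("'events' must contain a single session; build designs per session",
         call. = FALSE)
  }
  if (!is.numeric(TR) || TR <= 0) stop("'TR' must be positive", call. = FALSE)
  n_scans <- as.integer(n_scans)
  if (n_scans < 1L) stop("'n_scans' must be at least 1", call. = FALSE)
  oversampling <- as.integer(oversampling)
  dt <- TR / oversampling
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  total_time <- n_scans * TR

  if (any(events$onset >= total_time)) {
    stop("event onset at or beyond the end of the scanned interval", call. = FALSE)
  }
  if (any(events$onset + events$duration > total_time)) {
    warning("event extends beyond the last scan; regressor truncated", call. = FALSE)
  }

  n_fine <- n_scans * oversampling
  # convolved boxcar response per unique duration, on the microtime grid
  kernels <- lapply(unique(events$duration), function(d) {
    nd <- max(1L, as.integer(round(d / dt)))
    dt * convolve_open(rep(1, nd), hrf)
  })
  names(kernels) <- as.character(unique(events$duration))

  place <- function(onset, duration) {
    col <- numeric(n_fine)
    k <- kernels[[as.character(duration)]]
    b0 <- as.integer(round(onset / dt))          # 0-based bin of onset
    idx <- seq_len(min(length(k), n_fine - b0))
    if (length(idx)) col[b0 + idx] <- col[b0 + idx] + k[idx]
    col
  }

  tw <- events$is_trialwise
  trial_events <- events[tw, , drop = FALSE]
  trial_fine <- lapply(seq_len(nrow(trial_events)), function(i) {
    place(trial_events$onset[i], trial_events$duration[i])
  })

  nuis_conditions <- unique(events$condition[!tw])
  nuis_fine <- lapply(nuis_conditions, function(cond) {
    sel <- which(!tw & events$condition == cond)
    Reduce(`+`, lapply(sel, function(i) place(events$onset[i], events$duration[i])))
  })

  # sample at the middle microtime bin of each scan
  ref <- (seq_len(n_scans) - 1L) * oversampling + as.integer(floor(oversampling / 2)) + 1L
  cols <- c(trial_fine, nuis_fine)
  X <- if (length(cols)) {
    matrix(unlist(lapply(cols, function(v) v[ref])), nrow = n_scans)
  } else matrix(0, n_scans, 0)

  cn <- c(if (nrow(trial_events)) paste0("trial_", seq_len(nrow(trial_events))),
          if (length(nuis_conditions)) make.names(nuis_conditions))
  extra <- NULL
  if (!is.null(hpf_cutoff)) {
    extra <- dct_basis(n_scans, TR, hpf_cutoff)
    cn <- c(cn, colnames(extra))
  }
  if (constant) {
    extra <- cbind(extra, constant = rep(1, n_scans))
    cn <- c(cn, "constant")
  }
  X <- cbind(X, extra)
  colnames(X) <- cn

  if (!is.null(scan_cov)) check_scan_cov(scan_cov, n_scans)

  t <- nrow(trial_events)
  structure(list(matrix = X,
                 trial_cols = seq_len(t),
                 nuisance_cols = if (ncol(X) > t) seq.int(t + 1L, ncol(X)) else integer(),
                 TR = TR, n_scans = n_scans, oversampling = oversampling,
                 scan_cov = scan_cov, trial_info = trial_events),
            class = "trialwise_design")
}

# full open (linear) convolution of two vectors
convolve_open <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

check_scan_cov <- function(V, n) {
  if (!is.matrix(V) || nrow(V) != n || ncol(V) != n) {
    stop("'scan_cov' must be an n_scans x n_scans matrix", call. = FALSE)
  }
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V)))) {
    stop("'scan_cov' must be symmetric", call. = FALSE)
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'scan_cov' must be positive definite", call. = FALSE)
  invisible(V)
}

#' AR(1) scan covariance
#'
#' Convenience constructor for a first-order autoregressive scan covariance
#' matrix \eqn{V_{ij} = \rho^{|i-j|}}, for use as \code{scan_cov} when
#' whitening real data with temporally autocorrelated noise.
#'
#' @param n_scans number of scans.
#' @param rho AR(1) coefficient in (-1, 1).
#' @return An \code{n_scans x n_scans} correlation matrix.
#' @export
ar1_scan_cov <- function(n_scans, rho) {
  if (abs(rho) >= 1) stop("'rho' must lie in (-1, 1)", call. = FALSE)
  rho^abs(outer(seq_len(n_scans), seq_len(n_scans), `-`))
}

# discrete cosine drift basis: functions slower than 'cutoff' seconds
dct_basis <- function(n_scans, TR, cutoff) {
  if (cutoff <= 0) stop("'hpf_cutoff' must be positive", call. = FALSE)
  k_max <- floor(2 * n_scans * TR / cutoff)
  if (k_max < 1) return(NULL)
  n <- seq_len(n_scans) - 0.5
  B <- vapply(seq_len(k_max), function(k) {
    sqrt(2 / n_scans) * cos(pi * k * n / n_scans)
  }, numeric(n_scans))
  colnames(B) <- paste0("dct_", seq_len(k_max))
  B
}

#' @export
print.trialwise_design <- function(x, ...) {
  cat("Trial-wise fMRI design matrix\n")
  cat(sprintf("  scans: %d (TR = %g s), regressors: %d (%d trial, %d nuisance)\n",
              x$n_scans, x$TR, ncol(x$matrix),
              length(x$trial_cols), length(x$nuisance_cols)))
  cat(sprintf("  scan covariance: %s\n",
              if (is.null(x$scan_cov)) "identity" else "user-supplied"))
  invisible(x)
}

#' Build the trial-to-condition transformation matrix
#'
#' Constructs the \code{t x p} matrix T that maps trial regressors onto design
#' variables: one indicator column per condition (entry 1 where the trial
#' belongs to that condition) and, optionally, one real-valued parametric
#' column per modulator, holding the per-trial modulator values. Under the
#' relation \code{X = Xt \%*\% T}, multiplying the trial-wise design by T
#' collapses trial regressors into the condition regressors (and parametric
#' modulator regressors) of a standard GLM.
#'
#' @param events an [event_table()], or \code{NULL} to take the trial events
#'   from \code{design}.
#' @param design the paired [build_trialwise_design()] object (optional if
#'   \code{events} is given; used for consistency checking).
#' @param modulators character vector of modulator column names in the event
#'   table to append as parametric columns.
#'
#' @return A \code{t x p} numeric matrix with condition/modulator column
#'   names and an attribute \code{"column_kind"} of values
#'   \code{"indicator"}/\code{"parametric"}.
#' @export
build_transformation_matrix <- function(events = NULL, design = NULL,
                                        modulators = character()) {
  if (is.null(events)) {
    if (is.null(design)) stop("supply 'events' or 'design'", call. = FALSE)
    trials <- design$trial_info
  } else {
    trials <- events[events$is_trialwise, , drop = FALSE]
    if (!is.null(design) && nrow(trials) != length(design$trial_cols)) {
      stop("event table and design disagree on the number of trials", call. = FALSE)
    }
  }
  if (nrow(trials) == 0L) stop("no trial-wise events", call. = FALSE)
  lev <- sort(unique(trials$condition))
  Tm <- vapply(lev, function(l) as.numeric(trials$condition == l),
               numeric(nrow(trials)))
  Tm <- matrix(Tm, nrow = nrow(trials), dimnames = list(NULL, lev))
  kind <- rep("indicator", length(lev))
  for (m in modulators) {
    if (!m %in% names(trials)) stop("modulator column not found: ", m, call. = FALSE)
    v <- as.numeric(trials[[m]])
    if (anyNA(v)) stop("modulator '", m, "' has missing values", call. = FALSE)
    Tm <- cbind(Tm, v)
    colnames(Tm)[ncol(Tm)] <- m
    kind <- c(kind, "parametric")
  }
  attr(Tm, "column_kind") <- kind
  Tm
}
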