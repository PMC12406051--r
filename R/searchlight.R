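#' Build a spherical searchlight index over a masked grid
#'
#' For every in-mask voxel, collects the in-mask voxels whose centers lie
#' within a given Euclidean radius (in mm, inclusive boundary) of that voxel's
#' center. Boundary voxels keep truncated spheres. Anisotropic voxels are
#' supported through per-axis voxel sizes.
#'
#' @param mask 3-D logical (or 0/1) array; non-empty.
#' @param radius searchlight radius in mm (>= 0).
#' @param voxel_size voxel edge lengths in mm, length 1 or 3 (default 1).
#'
#' @return An object of class \code{"searchlight_index"}: list with
#'   \code{centers} (linear voxel indices of in-mask voxels),
#'   \code{center_coords} (n x 3, 1-based), \code{neighbors} (per center, the
#'   positions of its searchlight voxels within the in-mask voxel ordering),
#'   \code{radius}, \code{voxel_size} and \code{dim}.
#' @export
build_searchlight_index <- function(mask, radius, voxel_size = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3-D array", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (radius < 0) stop("'radius' must be non-negative", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  dm <- dim(mask)

  # integer offsets whose mm distance is within the radius (inclusive)
  rng <- lapply(voxel_size, function(s) {
    m <- floor(radius / s + 1e-9)
    seq.int(-m, m)
  })
  off <- as.matrix(expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]]))
  d_mm <- sqrt(colSums((t(off) * voxel_size)^2))
  off <- off[d_mm <= radius + 1e-9, , drop = FALSE]

  centers <- which(mask)
  co <- arrayInd(centers, dm)
  n <- length(centers)
  rank <- integer(prod(dm))          # linear index -> in-mask position
  rank[centers] <- seq_len(n)

  nb <- matrix(NA_integer_, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    x <- co[, 1] + off[k, 1]; y <- co[, 2] + off[k, 2]; z <- co[, 3] + off[k, 3]
    ok <- x >= 1L & x <= dm[1] & y >= 1L & y <= dm[2] & z >= 1L & z <= dm[3]
    lin <- (z[ok] - 1L) * dm[1] * dm[2] + (y[ok] - 1L) * dm[1] + x[ok]
    pos <- rank[lin]
    pos[pos == 0L] <- NA_integer_
    nb[ok, k] <- pos
  }
  neighbors <- lapply(seq_len(n), function(i) sort(nb[i, !is.na(nb[i, ])]))

  structure(list(centers = centers, center_coords = co, neighbors = neighbors,
                 radius = radius, voxel_size = voxel_size, dim = dm,
                 mask = mask),
            class = "searchlight_index")
}

#' @export
print.searchlight_index <- function(x, ...) {
  sizes <- lengths(x$neighbors)
  cat(sprintf("Searchlight index: %d centers, radius %g mm, voxels %s mm\n",
              length(x$centers), x$radius,
              paste(x$voxel_size, collapse = "x")))
  cat(sprintf("  searchlight sizes: min %d, median %g, max %d voxels\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Run decoding in every searchlight
#'
#' Extracts the trials-by-voxels submatrix of every searchlight from the
#' trial estimates, runs leave-one-session-out decoding (ITEM inversion or
#' the linear SVM baseline) and assembles voxel-wise performance maps. For
#' classification one decoding-accuracy (and balanced-accuracy) map is
#' produced; for regression one predictive-correlation (and median absolute
#' error) map per target column. Searchlights below the minimum voxel count
#' yield missing values. The computation is deterministic given its inputs,
#' and the searchlights are independent of each other.
#'
#' @param estimates a [trial_estimates()] whose columns correspond to in-mask
#'   voxels in \code{which(mask)} order (see [mask_volumes()]).
#' @param index a [build_searchlight_index()] object.
#' @param targets per-trial labels, numeric targets, or a transformation
#'   matrix (see [item()]).
#' @param method \code{"item"} (default) or \code{"svm"} baseline.
#' @param metrics which maps to produce; defaults depend on the task:
#'   \code{c("DA","BA")} for classification, \code{c("CC","MAE")} for
#'   regression.
#' @param min_voxels minimum searchlight size (default 1).
#' @param ... passed to [item()] (e.g. \code{calibrate}, \code{fallback}).
#'
#' @return A named list of 3-D maps (arrays, \code{NA} outside the mask and
#'   at skipped centers), one per metric (and per target column for
#'   regression), with attributes \code{metric} and \code{radius}.
#' @export
run_searchlight <- function(estimates, index, targets, method = c("item", "svm"),
                            metrics = NULL, min_voxels = 1L, ...) {
  stopifnot(inherits(estimates, "trial_estimates"),
            inherits(index, "searchlight_index"))
  method <- match.arg(method)
  n_mask <- length(index$centers)
  if (ncol(estimates$gamma) != n_mask) {
    stop("estimates have ", ncol(estimates$gamma), " voxels but the mask has ",
         n_mask, " in-mask voxels", call. = FALSE)
  }
  tt <- parse_targets(targets, nrow(estimates$gamma))
  task <- tt$task
  if (is.null(metrics)) {
    metrics <- if (task == "classification") c("DA", "BA") else c("CC", "MAE")
  }
  map_names <- if (task == "classification") metrics
               else as.vector(outer(metrics, colnames(tt$T), paste, sep = "."))
  maps <- lapply(map_names, function(nm) array(NA_real_, dim = index$dim))
  names(maps) <- map_names

  for (i in seq_len(n_mask)) {
    cols <- index$neighbors[[i]]
    if (length(cols) < min_voxels) next
    est_i <- trial_estimates(estimates$gamma[, cols, drop = FALSE],
                             estimates$sessions, U = estimates$U,
                             method = estimates$method)
    vals <- tryCatch(
      decode_metrics(est_i, targets, tt, method, metrics, ...),
      error = function(e) NULL)
    if (is.null(vals)) next
    for (nm in names(vals)) maps[[nm]][index$centers[i]] <- vals[[nm]]
  }
  for (nm in names(maps)) {
    attr(maps[[nm]], "metric") <- nm
    attr(maps[[nm]], "radius") <- index$radius
  }
  maps
}

# one searchlight / ROI decoding -> named metric values
decode_metrics <- function(est, targets, tt, method, metrics, ...) {
  task <- tt$task
  out <- list()
  if (method == "item") {
    fit <- item(est, targets, ...)
    if (task == "classification") {
      truth <- true_labels(fit)
      lab <- classify(fit$predicted)
      if ("DA" %in% metrics) out$DA <- decoding_accuracy(lab, truth)
      if ("BA" %in% metrics) out$BA <- balanced_accuracy(lab, truth)
    } else {
      for (k in seq_len(ncol(fit$predicted))) {
        cn <- colnames(fit$predicted)[k]
        if ("CC" %in% metrics) {
          out[[paste0("CC.", cn)]] <- suppressWarnings(
            predictive_correlation(fit$predicted[, k], fit$actual[, k]))
        }
        if ("MAE" %in% metrics) {
          out[[paste0("MAE.", cn)]] <-
            median_absolute_error(fit$predicted[, k], fit$actual[, k])
        }
      }
    }
  } else {
    if (task == "classification") {
      lab_targets <- if (is.factor(targets) || is.character(targets)) {
        factor(targets)
      } else factor(tt$levels[max.col(tt$T, ties.method = "first")],
                    levels = tt$levels)
      cv <- svm_crossvalidate(est, lab_targets)
      if ("DA" %in% metrics) out$DA <- decoding_accuracy(as.integer(cv$predicted),
                                                         as.integer(cv$actual))
      if ("BA" %in% metrics) out$BA <- balanced_accuracy(as.integer(cv$predicted),
                                                         as.integer(cv$actual))
    } else {
      Tm <- tt$T
      for (k in seq_len(ncol(Tm))) {
        cv <- svm_crossvalidate(est, Tm[, k])
        cn <- colnames(Tm)[k]
        if ("CC" %in% metrics) {
          out[[paste0("CC.", cn)]] <- suppressWarnings(
            predictive_correlation(cv$predicted, cv$actual))
        }
        if ("MAE" %in% metrics) {
          out[[paste0("MAE.", cn)]] <- median_absolute_error(cv$predicted, cv$actual)
        }
      }
    }
  }
  out
}

#' Region-of-interest decoding
#'
#' Runs one leave-one-session-out decoding on all voxels of a region of
#' interest, with the same metrics as the searchlight engine.
#'
#' @param estimates a [trial_estimates()] whose columns are in-mask voxels in
#'   \code{which(mask)} order.
#' @param roi logical 3-D array (same grid as the mask) or integer vector of
#'   in-mask voxel positions.
#' @param targets per-trial labels / targets (see [item()]).
#' @param mask the analysis mask the estimates were extracted with (required
#'   when \code{roi} is an array).
#' @inheritParams run_searchlight
#' @return Named list of metric values.
#' @export
roi_decode <- function(estimates, roi, targets, mask = NULL,
                       method = c("item", "svm"), metrics = NULL, ...) {
  method <- match.arg(method)
  if (is.array(roi)) {
    if (is.null(mask)) stop("'mask' is required when 'roi' is an array", call. = FALSE)
    if (!all(dim(roi) == dim(mask))) stop("ROI and mask grids differ", call. = FALSE)
    roi <- which(as.logical(roi)[which(as.logical(mask))])
  }
  roi <- as.integer(roi)
  if (!length(roi)) stop("ROI contains no in-mask voxels", call. = FALSE)
  tt <- parse_targets(targets, nrow(estimates$gamma))
  if (is.null(metrics)) {
    metrics <- if (tt$task == "classification") c("DA", "BA") else c("CC", "MAE")
  }
  est <- trial_estimates(estimates$gamma[, roi, drop = FALSE],
                         estimates$sessions, U = estimates$U,
                         method = estimates$method)
  decode_metrics(est, targets, tt, method, metrics, ...)
}

#' Extract in-mask trial estimates from 4-D volumes
#'
#' Flattens per-session 4-D trial-estimate volumes (trials along the 4th
#' axis) into the trials x voxels matrices used by the decoding functions,
#' keeping voxels in \code{which(mask)} order.
#'
#' @param volumes list of 4-D arrays, one per session.
#' @param mask 3-D logical array congruent with the volumes.
#' @param sessions session ids (default \code{seq_along(volumes)}).
#' @param U optional named list of per-session uncorrelation matrices.
#' @param method estimator label.
#' @return A [trial_estimates()] object.
#' @export
mask_volumes <- function(volumes, mask, sessions = seq_along(volumes),
                         U = NULL, method = "LSA") {
  mask <- array(as.logical(mask), dim = dim(mask))
  vox <- which(mask)
  gam <- lapply(volumes, function(v) {
    if (!all(dim(v)[1:3] == dim(mask))) {
      stop("volume grid does not match the mask", call. = FALSE)
    }
    t(matrix(v, prod(dim(mask)), dim(v)[4])[vox, , drop = FALSE])
  })
  ses <- rep(as.character(sessions), vapply(gam, nrow, integer(1)))
  trial_estimates(do.call(rbind, gam), ses, U = U, method = method)
}
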