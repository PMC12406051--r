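#' Configuration of the synthetic searchlight generator
#'
#' Bundles the parameters of the rapid event-related generative model used in
#' the method-comparison studies: per session, a balanced random condition
#' sequence is drawn; per voxel, condition-mean responses are standard normal
#' with only a proportion \code{info_proportion} of voxels differing between
#' conditions; per trial, amplitudes are normal around the voxel's condition
#' mean with standard deviation \code{amp_sd}; inter-stimulus intervals are
#' uniform on \code{isi_range}; the multivariate signal is the trial-wise
#' design (HRF-convolved boxcars of \code{stim_duration} seconds, sampled at
#' \code{TR}) times the amplitudes plus white Gaussian noise of variance
#' \code{noise_var}.
#'
#' @param n_sessions number of fMRI sessions S (default 2).
#' @param trials_per_session trials per session t (default 100).
#' @param n_voxels voxels per searchlight v (default 33, a radius-2 sphere).
#' @param info_proportion proportion r of informative voxels in [0,1]
#'   (default 0.2).
#' @param amp_sd trial-to-trial amplitude standard deviation (default 0.5).
#' @param noise_var scan noise variance (default 0.8).
#' @param isi_range inter-stimulus interval bounds in seconds (default
#'   \code{c(0, 4)}).
#' @param stim_duration stimulus duration in seconds (default 2).
#' @param TR repetition time in seconds (default 2).
#' @param n_conditions number of experimental conditions (default 2).
#' @param hrf_tail seconds of scanning appended after the last trial so the
#'   final HRF is covered (default 32).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_sessions = 2L, trials_per_session = 100L,
                       n_voxels = 33L, info_proportion = 0.2, amp_sd = 0.5,
                       noise_var = 0.8, isi_range = c(0, 4),
                       stim_duration = 2, TR = 2, n_conditions = 2L,
                       hrf_tail = 32) {
  stopifnot(n_sessions >= 1, trials_per_session >= 2, n_voxels >= 1)
  if (info_proportion < 0 || info_proportion > 1) {
    stop("'info_proportion' must lie in [0, 1]", call. = FALSE)
  }
  if (amp_sd <= 0) stop("'amp_sd' must be positive", call. = FALSE)
  if (noise_var <= 0) stop("'noise_var' must be positive", call. = FALSE)
  if (length(isi_range) != 2L || isi_range[2] <= isi_range[1] || isi_range[1] < 0) {
    stop("'isi_range' must be (a, b) with b > a >= 0", call. = FALSE)
  }
  stopifnot(stim_duration > 0, TR > 0, n_conditions >= 2)
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 n_voxels = as.integer(n_voxels),
                 info_proportion = info_proportion, amp_sd = amp_sd,
                 noise_var = noise_var, isi_range = as.numeric(isi_range),
                 stim_duration = stim_duration, TR = TR,
                 n_conditions = as.integer(n_conditions),
                 hrf_tail = hrf_tail),
            class = "sim_config")
}

# generative core shared by the searchlight and the volume simulators;
# info_idx gives the voxels whose condition means differ
sim_core <- function(config, v, info_idx) {
  nc <- config$n_conditions
  mu <- matrix(stats::rnorm(v), v, nc)      # condition A means, recycled
  if (length(info_idx)) {
    for (c in seq_len(nc)[-1]) {
      mu[info_idx, c] <- stats::rnorm(length(info_idx))
    }
  }
  t <- config$trials_per_session
  lev <- LETTERS[seq_len(nc)]

  sessions <- lapply(seq_len(config$n_sessions), function(s) {
    counts <- diff(floor(t * (0:nc) / nc))
    labels <- sample(rep(seq_len(nc), times = counts))
    isi <- stats::runif(t, config$isi_range[1], config$isi_range[2])
    onsets <- c(0, cumsum(config$stim_duration + isi[-t]))
    n_scans <- ceiling((onsets[t] + config$stim_duration + config$hrf_tail) /
                         config$TR)
    ev <- event_table(onset = onsets, duration = config$stim_duration,
                      condition = lev[labels], session = s)
    des <- build_trialwise_design(ev, n_scans = n_scans, TR = config$TR)
    gam <- mu[, labels, drop = FALSE] +
      stats::rnorm(t * v, sd = config$amp_sd)
    gam <- t(gam)                            # t x v true amplitudes
    Xt <- des$matrix[, des$trial_cols, drop = FALSE]
    Y <- Xt %*% gam + matrix(stats::rnorm(n_scans * v,
                                          sd = sqrt(config$noise_var)),
                             n_scans, v)
    list(signal = Y, labels = factor(lev[labels], levels = lev),
         gamma = gam, design = des)
  })
  list(mu = mu, sessions = sessions, levels = lev)
}

#' Generate one synthetic searchlight dataset
#'
#' Draws one dataset from the generative model described in [sim_config()]:
#' per-session signals, true trial amplitudes, condition labels and trial-wise
#' designs for a single searchlight of \code{n_voxels} voxels.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (set before all draws).
#' @return An object of class \code{"sim_searchlight"}: lists \code{signals},
#'   \code{labels}, \code{true_gamma}, \code{designs} (one element per
#'   session), plus \code{mu} (voxel x condition means),
#'   \code{info_voxels} and \code{config}.
#' @export
simulate_searchlight <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  v <- config$n_voxels
  k_exact <- config$info_proportion * v
  k <- as.integer(round(k_exact))
  if (abs(k_exact - k) > 1e-9) {
    message("informative voxel count ", signif(k_exact, 4),
            " rounded to ", k)
  }
  info_idx <- if (k > 0) sample(v, k) else integer()
  core <- sim_core(config, v, info_idx)
  structure(list(signals = lapply(core$sessions, `[[`, "signal"),
                 labels = lapply(core$sessions, `[[`, "labels"),
                 true_gamma = lapply(core$sessions, `[[`, "gamma"),
                 designs = lapply(core$sessions, `[[`, "design"),
                 mu = core$mu, info_voxels = sort(info_idx),
                 config = config),
            class = "sim_searchlight")
}

#' @export
print.sim_searchlight <- function(x, ...) {
  cat(sprintf(paste0("Synthetic searchlight: %d sessions x %d trials, %d voxels ",
                     "(%d informative), %d conditions\n"),
              length(x$signals), x$config$trials_per_session,
              x$config$n_voxels, length(x$info_voxels), x$config$n_conditions))
  invisible(x)
}

#' Generate a synthetic volume with an embedded informative sphere
#'
#' Extends the searchlight generator to a full 3-D grid: every voxel gets a
#' signal, but only voxels inside a sphere around \code{center} carry
#' condition information. Used to check that searchlight decoding localizes
#' the informative region.
#'
#' @param config a [sim_config()] (its \code{n_voxels} is ignored).
#' @param dim grid dimensions (default \code{c(10, 10, 10)}).
#' @param center sphere center in voxel coordinates (1-based).
#' @param radius sphere radius in voxels.
#' @param seed optional integer seed.
#' @return A \code{"sim_searchlight"} with extra fields \code{dim},
#'   \code{center}, \code{mask} (all-true) and \code{info_voxels} indexing
#'   \code{which(mask)}.
#' @export
simulate_searchlight_volume <- function(config, dim = c(10, 10, 10),
                                        center = ceiling(dim / 2), radius = 2,
                                        seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  v <- prod(dim)
  co <- arrayInd(seq_len(v), dim)
  d <- sqrt(colSums((t(co) - center)^2))
  info_idx <- which(d <= radius + 1e-9)
  core <- sim_core(config, v, info_idx)
  structure(list(signals = lapply(core$sessions, `[[`, "signal"),
                 labels = lapply(core$sessions, `[[`, "labels"),
                 true_gamma = lapply(core$sessions, `[[`, "gamma"),
                 designs = lapply(core$sessions, `[[`, "design"),
                 mu = core$mu, info_voxels = info_idx,
                 dim = dim, center = center,
                 mask = array(TRUE, dim = dim),
                 config = config),
            class = "sim_searchlight")
}

#' Decode one simulated dataset with each method
#'
#' Runs the four trial-wise decoding routes on a simulated dataset: LS-A,
#' LS-S and the fractional-ridge baseline feed their amplitude estimates to a
#' cross-validated linear SVM; ITEM uses LS-A estimates and inverts the
#' transformed encoding model with the ReML-calibrated uncorrelation matrix.
#' Decoding accuracy is pooled over all sessions.
#'
#' @param sim a [simulate_searchlight()] result.
#' @param methods subset of \code{c("LSA", "LSS", "ITEM", "FRACRIDGE")}.
#' @return Named numeric vector of decoding accuracies.
#' @export
decode_simulation <- function(sim, methods = c("LSA", "LSS", "ITEM", "FRACRIDGE")) {
  bad <- setdiff(methods, c("LSA", "LSS", "ITEM", "FRACRIDGE"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  labels <- factor(unlist(lapply(sim$labels, as.character)),
                   levels = levels(sim$labels[[1]]))
  S <- length(sim$signals)
  acc <- c()
  lsa <- NULL
  if (any(c("LSA", "ITEM") %in% methods)) {
    lsa <- combine_trial_estimates(lapply(seq_len(S), function(s) {
      lsa_estimate(sim$signals[[s]], sim$designs[[s]])
    }))
  }
  svm_da <- function(est) {
    cv <- svm_crossvalidate(est, labels)
    decoding_accuracy(as.integer(cv$predicted), as.integer(cv$actual))
  }
  if ("LSA" %in% methods) acc["LSA"] <- svm_da(lsa)
  if ("LSS" %in% methods) {
    lss <- combine_trial_estimates(lapply(seq_len(S), function(s) {
      lss_estimate(sim$signals[[s]], sim$designs[[s]])
    }))
    acc["LSS"] <- svm_da(lss)
  }
  if ("FRACRIDGE" %in% methods) {
    fr <- fracridge_estimate(sim$signals, sim$designs)
    acc["FRACRIDGE"] <- svm_da(fr)
  }
  if ("ITEM" %in% methods) {
    fit <- item(lsa, labels, calibrate = TRUE)
    acc["ITEM"] <- decoding_accuracy(classify(fit$predicted), true_labels(fit))
  }
  acc[methods]
}

#' Compare trial-wise decoding methods across simulations
#'
#' Repeats [simulate_searchlight()] + [decode_simulation()] N times under a
#' master seed. Per-simulation seeds are drawn once from the master seed, so
#' increasing N extends rather than reshuffles the simulation set.
#'
#' @param config a [sim_config()].
#' @param methods methods to compare.
#' @param N number of simulations.
#' @param seed master seed.
#' @return A long-format data frame with columns \code{sim}, \code{method},
#'   \code{accuracy}.
#' @export
run_method_comparison <- function(config, methods = c("LSA", "LSS", "ITEM",
                                                      "FRACRIDGE"),
                                  N = 100L, seed = 1L) {
  bad <- setdiff(methods, c("LSA", "LSS", "ITEM", "FRACRIDGE"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (config$n_sessions < 2L) {
    stop("cross-validation requires at least 2 sessions", call. = FALSE)
  }
  set.seed(seed)
  seeds <- floor(stats::runif(N) * .Machine$integer.max)
  res <- vector("list", N)
  for (i in seq_len(N)) {
    sim <- simulate_searchlight(config, seed = seeds[i])
    acc <- decode_simulation(sim, methods)
    res[[i]] <- data.frame(sim = i, method = names(acc), accuracy = unname(acc))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Accuracy-versus-information curves
#'
#' Sweeps searchlight size, trial count and the proportion of informative
#' voxels, recording mean and standard deviation of decoding accuracy per
#' grid point and method.
#'
#' @param base_config a [sim_config()] supplying all non-swept parameters.
#' @param v_grid,t_grid,r_grid grids for voxels per searchlight, trials per
#'   session and information proportion.
#' @param N simulations per grid point.
#' @param methods methods to compare.
#' @param seed master seed (per-point seeds derived from it).
#' @return Data frame with columns \code{v}, \code{t}, \code{r},
#'   \code{method}, \code{mean_da}, \code{sd_da}.
#' @export
sweep_information_curves <- function(base_config, v_grid, t_grid, r_grid,
                                     N = 100L,
                                     methods = c("LSA", "LSS", "ITEM",
                                                 "FRACRIDGE"),
                                     seed = 1L) {
  if (!length(v_grid) || !length(t_grid) || !length(r_grid)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(v = v_grid, t = t_grid, r = r_grid)
  set.seed(seed)
  point_seeds <- floor(stats::runif(nrow(grid)) * .Machine$integer.max)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- base_config
    cfg$n_voxels <- as.integer(grid$v[g])
    cfg$trials_per_session <- as.integer(grid$t[g])
    cfg$info_proportion <- grid$r[g]
    res <- run_method_comparison(cfg, methods, N = N, seed = point_seeds[g])
    agg_m <- tapply(res$accuracy, res$method, mean)
    agg_s <- tapply(res$accuracy, res$method, stats::sd)
    data.frame(v = grid$v[g], t = grid$t[g], r = grid$r[g],
               method = names(agg_m), mean_da = unname(agg_m),
               sd_da = unname(agg_s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
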