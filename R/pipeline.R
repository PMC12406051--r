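#' Run a full trial-wise decoding pipeline from a configuration
#'
#' Executes design construction, trial-wise estimation and decoding (ROI or
#' searchlight) from a single configuration, writing results and a run
#' manifest to an output directory. The configuration is a named list, or a
#' path to a JSON/YAML file with the same fields:
#'
#' \describe{
#'   \item{mode}{\code{"simulate"} or \code{"decode"}.}
#'   \item{simulate mode}{\code{n_sims}, \code{seed}, plus any [sim_config()]
#'     fields (\code{noise_var}, \code{isi_range}, ...) and \code{methods}.}
#'   \item{decode mode}{\code{events} and \code{data} (per-session file
#'     paths), \code{mask}, \code{TR}, \code{estimator} (\code{"LSA"},
#'     \code{"LSS"} or \code{"FRACRIDGE"}), \code{task}
#'     (\code{"classification"}/\code{"regression"}), optional
#'     \code{modulators} (column names), \code{radius_mm} for searchlight
#'     decoding or \code{roi} (mask path) for ROI decoding,
#'     \code{hpf_cutoff}, \code{method} (\code{"item"}/\code{"svm"}).}
#'   \item{out_dir}{output directory (created if missing).}
#' }
#'
#' @param config named list or path to a JSON/YAML configuration file.
#' @return Invisibly, a list of produced artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- cfg$mode %||% "decode"
  artifacts <- switch(mode,
    simulate = stage("simulate", pipeline_simulate(cfg, out_dir)),
    decode = pipeline_decode(cfg, out_dir),
    stop("[config] unknown mode: ", mode, call. = FALSE))
  manifest <- list(package = "itemsl",
                   version = as.character(utils::packageVersion("itemsl")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = cfg, artifacts = artifacts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(artifacts, manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("[config] file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("[config] the 'yaml' package is required for YAML configs", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("[config] configuration must be a list or a file path",
                             call. = FALSE)
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

pipeline_simulate <- function(cfg, out_dir) {
  fields <- intersect(names(cfg), names(formals(sim_config)))
  sc <- do.call(sim_config, cfg[fields])
  methods <- cfg$methods %||% c("LSA", "LSS", "ITEM", "FRACRIDGE")
  res <- run_method_comparison(sc, methods = methods,
                               N = cfg$n_sims %||% 100L,
                               seed = cfg$seed %||% 1L)
  tsv <- file.path(out_dir, "simulation_accuracies.tsv")
  utils::write.table(res, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(accuracies = tsv)
}

pipeline_decode <- function(cfg, out_dir) {
  for (f in c("events", "data", "mask", "TR")) {
    if (is.null(cfg[[f]])) stop("[config] missing field: ", f, call. = FALSE)
  }
  if (length(cfg$events) != length(cfg$data)) {
    stop("[config] 'events' and 'data' must list one file per session", call. = FALSE)
  }
  mask_img <- stage("io", read_volume(cfg$mask))
  mask <- array(as.logical(mask_img > 0), dim = dim(mask_img)[1:3])
  vox <- which(mask)
  S <- length(cfg$data)
  estimator <- toupper(cfg$estimator %||% "LSA")

  sessions <- stage("design", lapply(seq_len(S), function(s) {
    vol <- read_volume(cfg$data[[s]])
    check_same_grid(vol, mask_img)
    n_scans <- dim(vol)[4]
    ev <- read_events(cfg$events[[s]], session = s,
                      modulator_columns = cfg$modulators %||% character())
    des <- build_trialwise_design(ev, n_scans = n_scans, TR = cfg$TR,
                                  hpf_cutoff = cfg$hpf_cutoff)
    Y <- t(matrix(vol, prod(dim(mask)), n_scans)[vox, , drop = FALSE])
    list(events = ev, design = des, signal = Y)
  }))

  est <- stage("estimate", {
    if (estimator == "FRACRIDGE") {
      fracridge_estimate(lapply(sessions, `[[`, "signal"),
                         lapply(sessions, `[[`, "design"))
    } else {
      fn <- if (estimator == "LSS") lss_estimate else lsa_estimate
      combine_trial_estimates(lapply(sessions, function(s) {
        fn(s$signal, s$design)
      }))
    }
  })

  est_paths <- stage("estimate", {
    paths <- character(S)
    at <- 0L
    for (s in seq_len(S)) {
      t_s <- sum(est$sessions == unique(est$sessions)[s])
      vol4 <- array(NA_real_, dim = c(dim(mask), t_s))
      flat <- matrix(vol4, prod(dim(mask)), t_s)
      flat[vox, ] <- t(est$gamma[at + seq_len(t_s), , drop = FALSE])
      vol4 <- array(flat, dim = c(dim(mask), t_s))
      paths[s] <- file.path(out_dir, sprintf("estimates_ses-%02d.nii.gz", s))
      write_volume(vol4, paths[s], template = mask_img)
      at <- at + t_s
    }
    sidecar <- file.path(out_dir, "estimates.json")
    jsonlite::write_json(list(method = est$method, sessions = S,
                              files = basename(paths)),
                         sidecar, auto_unbox = TRUE, pretty = TRUE)
    c(paths, sidecar)
  })

  targets <- stage("decode", {
    ev_all <- do.call(rbind, lapply(sessions, `[[`, "events"))
    task <- cfg$task %||% "classification"
    if (task == "regression") {
      if (is.null(cfg$modulators)) {
        stop("regression decoding needs 'modulators'", call. = FALSE)
      }
      Tm <- do.call(rbind, lapply(sessions, function(s) {
        build_transformation_matrix(s$events, modulators = cfg$modulators)
      }))
      Tm[, cfg$modulators, drop = FALSE]
    } else {
      factor(ev_all$condition[ev_all$is_trialwise])
    }
  })

  decode_method <- cfg$method %||% "item"
  artifacts <- stage("decode", {
    if (!is.null(cfg$roi)) {
      roi_img <- read_volume(cfg$roi)
      check_same_grid(roi_img, mask_img)
      vals <- roi_decode(est, array(roi_img > 0, dim = dim(mask)), targets,
                         mask = mask, method = decode_method)
      js <- file.path(out_dir, "roi_decoding.json")
      jsonlite::write_json(vals, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(roi_results = js)
    } else {
      radius <- cfg$radius_mm %||% 6
      vsz <- tryCatch(RNifti::pixdim(mask_img)[1:3], error = function(e) c(1, 1, 1))
      idx <- build_searchlight_index(mask, radius, voxel_size = vsz)
      maps <- run_searchlight(est, idx, targets, method = decode_method,
                              min_voxels = cfg$min_voxels %||% 1L)
      paths <- vapply(names(maps), function(nm) {
        p <- file.path(out_dir, paste0("map_", gsub("[^A-Za-z0-9._-]", "_", nm),
                                       ".nii.gz"))
        write_volume(array(maps[[nm]], dim = dim(mask)), p, template = mask_img)
        p
      }, character(1))
      paths
    }
  })
  c(est_paths, artifacts)
}
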