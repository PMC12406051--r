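#' Canonical haemodynamic response function
#'
#' Samples the canonical double-gamma haemodynamic response function (HRF) on a
#' regular time grid. The kernel is the difference of two gamma densities in
#' the SPM convention (response delay 6 s, undershoot delay 16 s, both
#' dispersions 1 s, response-to-undershoot ratio 6) and is peak-normalized so
#' that its maximum equals 1. The response peaks at roughly 5--6 s after
#' stimulus onset and shows a post-stimulus undershoot that has returned to
#' baseline by about 32 s.
#'
#' @param sampling_interval grid spacing in seconds (e.g. \code{TR/16} for a
#'   microtime grid). Must be positive.
#' @param length kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds).
#' @param peak_disp,undershoot_disp gamma dispersions (seconds).
#' @param ratio response-to-undershoot amplitude ratio.
#'
#' @return A numeric vector of kernel values at times
#'   \code{seq(0, length, by = sampling_interval)}, with \code{max(.) == 1}.
#'   The time grid is attached as attribute \code{"time"}.
#'
#' @examples
#' h <- canonical_hrf(0.1)
#' attr(h, "time")[which.max(h)]  # peak around 5 s
#'
#' @export
canonical_hrf <- function(sampling_interval, length = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 6) {
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      !is.finite(sampling_interval) || sampling_interval <= 0) {
    stop("'sampling_interval' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(length) || length <= 0) {
    stop("'length' must be a positive number of seconds", call. = FALSE)
  }
  tt <- seq(0, length, by = sampling_interval)
  h <- stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
  h <- h / max(h)
  attr(h, "time") <- tt
  h
}
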