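#' Trial event tables
#'
#' An event table records, per fMRI session, the onset (seconds from the start
#' of the first scan, 0-based), duration (seconds), condition label and
#' optional parametric modulator values of every stimulus event. Events can be
#' flagged trial-wise (each event gets its own regressor in the trial-wise
#' design) or not (events of the same condition are pooled into one condition
#' regressor, as for nuisance events such as cues).
#'
#' @param onset numeric vector of event onsets in seconds (non-negative,
#'   strictly increasing within a session).
#' @param duration numeric vector (positive) or scalar, seconds.
#' @param condition character or factor of condition labels, one per event.
#' @param session integer session id per event (default all 1).
#' @param is_trialwise logical per event (default \code{TRUE}): does this
#'   event receive its own trial regressor?
#' @param modulators optional data frame (or named list) of per-event numeric
#'   modulator values.
#'
#' @return A data frame of class \code{"event_table"} with columns
#'   \code{session}, \code{onset}, \code{duration}, \code{condition},
#'   \code{is_trialwise} and one column per modulator.
#' @export
event_table <- function(onset, duration, condition, session = 1L,
                        is_trialwise = TRUE, modulators = NULL) {
  n <- length(onset)
  if (n == 0L) stop("event table must contain at least one event", call. = FALSE)
  duration <- rep_len(duration, n)
  session <- rep_len(as.integer(session), n)
  is_trialwise <- rep_len(as.logical(is_trialwise), n)
  if (!length(condition) %in% c(1L, n)) {
    stop("'condition' must have one label per event", call. = FALSE)
  }
  condition <- rep_len(as.character(condition), n)
  ev <- data.frame(session = session, onset = as.numeric(onset),
                   duration = as.numeric(duration), condition = condition,
                   is_trialwise = is_trialwise, stringsAsFactors = FALSE)
  if (!is.null(modulators)) {
    modulators <- as.data.frame(modulators)
    if (nrow(modulators) != n) stop("modulators must have one row per event", call. = FALSE)
    bad <- intersect(names(modulators), names(ev))
    if (length(bad)) stop("modulator names clash with reserved columns: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    ev <- cbind(ev, modulators)
  }
  validate_event_table(ev)
  class(ev) <- c("event_table", "data.frame")
  ev
}

validate_event_table <- function(ev) {
  if (nrow(ev) == 0L) stop("event table is empty", call. = FALSE)
  if (any(ev$onset < 0)) stop("event onsets must be non-negative", call. = FALSE)
  if (any(ev$duration <= 0)) stop("event durations must be positive", call. = FALSE)
  for (s in unique(ev$session)) {
    o <- ev$onset[ev$session == s]
    if (is.unsorted(o, strictly = TRUE)) {
      stop("event onsets must be strictly increasing within session ", s, call. = FALSE)
    }
  }
  invisible(ev)
}

#' Read a BIDS-style events.tsv file
#'
#' Reads a tab-separated events file in the BIDS dialect (columns
#' \code{onset}, \code{duration}, \code{trial_type}, plus arbitrary numeric
#' modulator columns) into an [event_table()].
#'
#' @param path path to an events .tsv file.
#' @param session integer session id assigned to all events in the file.
#' @param modulator_columns character vector naming columns to carry along as
#'   parametric modulators (default: none).
#' @param trialwise_conditions conditions to break up into trials; default all.
#'
#' @return An \code{event_table}.
#' @export
read_events <- function(path, session = 1L, modulator_columns = character(),
                        trialwise_conditions = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  tsv <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(tsv))
  if (length(miss)) stop("events file lacks required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(modulator_columns, names(tsv))
  if (length(miss)) stop("modulator column(s) not found: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tw <- if (is.null(trialwise_conditions)) TRUE else tsv$trial_type %in% trialwise_conditions
  mods <- if (length(modulator_columns)) tsv[modulator_columns] else NULL
  event_table(onset = tsv$onset, duration = tsv$duration,
              condition = tsv$trial_type, session = session,
              is_trialwise = tw, modulators = mods)
}
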