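# Spike/event containers and the window conventions shared by every
# estimator. Spike membership in an event window is half-open on the left:
# a spike x belongs to event w iff w + t0 < x <= w + t1.

#' Stitch out unobserved time between event windows
#'
#' Removes spikes that fall between consecutive event windows and compensates
#' by shifting the remaining spike times and all event times backwards by the
#' cumulative excluded duration. After stitching, no inter-event gap exceeds
#' the window duration `t1 - t0`, while the position of every retained spike
#' relative to its event is unchanged. Spikes before the first event's window
#' or after the last event's window carry no event-relative information and
#' are dropped.
#'
#' Stitching keeps the resampled (event-jittered) data used for significance
#' testing structurally comparable to the observed data: without it, jittered
#' events could recruit spikes from epochs that the analysis window never
#' covers.
#'
#' @param spikes Numeric vector of spike times in seconds, or a data frame
#'   with a `spike_time_s` column.
#' @param events Numeric vector of event times in seconds, or a data frame
#'   with an `event_time_s` column.
#' @param t0,t1 Analysis window bounds in seconds, relative to each event.
#' @param initial Logical; validate the window as an initial analysis window
#'   (must straddle the event time). Internal iterative calls set this to
#'   `FALSE`.
#'
#' @return A list with elements `spikes` (adjusted spike times), `events`
#'   (adjusted event times) and `excluded` (the excised duration after each
#'   of the first `q - 1` events; all zero when windows tile or overlap).
#'
#' @examples
#' stitch_spikes(c(0.5, 5.0, 10.5), c(0, 10), t0 = -0.1, t1 = 1)
#' @export
stitch_spikes <- function(spikes, events, t0, t1, initial = FALSE) {
  spikes <- as_spike_times(spikes)
  events <- as_event_times(events)
  check_window(t0, t1, initial = initial)
  dur <- t1 - t0
  q <- length(events)
  gaps <- if (q >= 2L) pmax(diff(events) - dur, 0) else numeric(0)
  shift <- c(0, cumsum(gaps))
  # Assign each spike to the latest event whose window it can belong to,
  # then keep it only if it is inside that window. Spikes in excised gaps
  # fail the right-bound test; spikes before the first window get k = 0.
  k <- findInterval(spikes, events + t0, left.open = TRUE)
  inside <- k >= 1L & spikes <= events[pmax(k, 1L)] + t1
  list(
    spikes = spikes[inside] - shift[k[inside]],
    events = events - shift,
    excluded = gaps
  )
}

#' Align spikes to event times
#'
#' Pools event-relative spike times across events: every spike with
#' `w + t0 < x <= w + t1` contributes `x - w` for each event `w` whose window
#' contains it (a spike inside two overlapping windows contributes once per
#' window). Duplicate relative times from multi-unit data are retained.
#'
#' @inheritParams stitch_spikes
#' @return Sorted numeric vector of event-relative spike times in
#'   `(t0, t1]`; may be empty.
#' @examples
#' align_spikes(c(1.2, 2.3), c(1, 2), t0 = 0, t1 = 1)
#' @export
align_spikes <- function(spikes, events, t0, t1) {
  spikes <- as_spike_times(spikes)
  events <- as_event_times(events)
  check_window(t0, t1, initial = FALSE)
  lo <- findInterval(events + t0, spikes) # spikes <= w + t0 are excluded
  hi <- findInterval(events + t1, spikes) # spikes <= w + t1 are included
  counts <- hi - lo
  idx <- sequence(counts, from = lo + 1L)
  sort(spikes[idx] - rep(events, counts))
}

# As align_spikes() but keeping the per-event structure: returns a list with
# one (possibly empty, internally sorted) vector of relative times per event.
# Used to build the trial-swap permutation null of the two-sample estimator.
align_spikes_by_event <- function(spikes, events, t0, t1) {
  spikes <- as_spike_times(spikes)
  events <- as_event_times(events)
  check_window(t0, t1, initial = FALSE)
  lo <- findInterval(events + t0, spikes)
  hi <- findInterval(events + t1, spikes)
  counts <- hi - lo
  idx <- sequence(counts, from = lo + 1L)
  rel <- spikes[idx] - rep(events, counts)
  f <- factor(rep(seq_along(events), counts), levels = seq_along(events))
  unname(split(rel, f))
}

#' Add artificial boundary spikes at the window edges
#'
#' Prepends `t0` and appends `t1` to a vector of event-relative spike times so
#' the cumulative-fraction curve covers the full analysis epoch. A relative
#' spike time already equal to `t1` is kept as a duplicate; the output always
#' has `length(v) + 2` elements.
#'
#' @param v Sorted numeric vector of event-relative spike times in `(t0, t1]`.
#' @param t0,t1 Window bounds in seconds.
#' @return Sorted numeric vector `c(t0, v, t1)`.
#' @export
add_boundary_spikes <- function(v, t0, t1) {
  check_window(t0, t1, initial = FALSE)
  c(t0, v, t1)
}

#' Read spike times from a delimited text file
#'
#' Expects one spike per row with a `spike_time_s` column (CSV by default).
#'
#' @param path Path to the file.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
read_spike_times <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(spike_time_s = readr::col_double()))
  as_spike_times(df)
}

#' Read event times (and optional condition labels) from a delimited file
#'
#' Expects an `event_time_s` column and an optional `condition` column.
#'
#' @param path Path to the file.
#' @return A tibble with `event_time_s` (sorted) and, when present in the
#'   file, `condition`.
#' @export
read_event_times <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  if (!"event_time_s" %in% names(df)) {
    abort("Events file must have an `event_time_s` column.")
  }
  keep <- intersect(c("event_time_s", "condition"), names(df))
  df <- df[keep]
  df[order(df$event_time_s), , drop = FALSE]
}

#' Write spike times to CSV
#'
#' Times are written with microsecond precision, far below the temporal
#' resolution of any latency estimate.
#'
#' @param spikes Numeric vector of spike times in seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(spikes, path) {
  spikes <- as_spike_times(spikes)
  readr::write_csv(tibble(spike_time_s = round(spikes, 6)), path)
  invisible(path)
}

#' Write event times (and optional condition labels) to CSV
#'
#' @param events Numeric vector of event times, or a data frame with
#'   `event_time_s` and optionally `condition`.
#' @param path Output path.
#' @param condition Optional character vector of per-event condition labels
#'   (used when `events` is a bare vector).
#' @return `path`, invisibly.
#' @export
write_event_times <- function(events, path, condition = NULL) {
  if (is.data.frame(events)) {
    df <- events
  } else {
    df <- tibble(event_time_s = as.double(events))
    if (!is.null(condition)) df$condition <- condition
  }
  df$event_time_s <- round(df$event_time_s, 6)
  readr::write_csv(df, path)
  invisible(path)
}
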