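# Internal helpers: input coercion, window validation, seed management.

# Accept a bare numeric vector or a data frame with a `spike_time_s` column.
as_spike_times <- function(spikes, arg = "spikes") {
  if (is.data.frame(spikes)) {
    if (!"spike_time_s" %in% names(spikes)) {
      abort(sprintf("`%s` data frame must have a `spike_time_s` column.", arg))
    }
    spikes <- spikes[["spike_time_s"]]
  }
  spikes <- as.double(spikes)
  if (anyNA(spikes) || any(is.infinite(spikes))) {
    abort(sprintf("`%s` must contain only finite spike times.", arg))
  }
  if (is.unsorted(spikes)) spikes <- sort(spikes)
  spikes
}

as_event_times <- function(events, arg = "events") {
  if (is.data.frame(events)) {
    if (!"event_time_s" %in% names(events)) {
      abort(sprintf("`%s` data frame must have an `event_time_s` column.", arg))
    }
    events <- events[["event_time_s"]]
  }
  events <- as.double(events)
  if (length(events) < 1L) {
    abort(sprintf("`%s` must contain at least one event time.", arg))
  }
  if (anyNA(events) || any(is.infinite(events))) {
    abort(sprintf("`%s` must contain only finite event times.", arg))
  }
  if (is.unsorted(events)) events <- sort(events)
  events
}

# The initial analysis window must straddle the event time: either t0 <= 0 and
# t1 > 0, or t0 < 0 and t1 >= 0. Narrowed windows inside the iterative loop
# only need positive duration.
check_window <- function(t0, t1, initial = TRUE) {
  if (!is.finite(t0) || !is.finite(t1)) {
    abort("Window bounds `t0` and `t1` must be finite.")
  }
  if (t1 <= t0) {
    abort("Window duration must be positive (`t1` > `t0`).")
  }
  if (initial && !((t0 <= 0 && t1 > 0) || (t0 < 0 && t1 >= 0))) {
    abort("Initial window must contain the event time: need t0 <= 0 < t1 (or t0 < 0 <= t1).")
  }
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state when `seed` is given, restoring
# the caller's stream afterwards; pass-through when seed is NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-resample seed streams: resample m of a loop with base seed
# s uses seed (s + m) mod (2^31 - 1), so growing the number of resamples never
# perturbs earlier draws. Iteration l of an estimator offsets the base by
# 7919 * l (larger than any default resample count) to keep streams disjoint.
counter_seed <- function(base, counter) {
  if (is.null(base)) return(NULL)
  as.integer((as.double(base) + counter) %% 2147483647)
}

iteration_seed <- function(seed, iteration) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 7919 * iteration) %% 2147483647)
}
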