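# Two-sample divergence-latency estimator: per-event-normalized cumulative
# spike counts on a merged time grid, linear detrending, and a trial-swap
# permutation null, wrapped in the same iterative window refinement as the
# one-sample estimator.

#' Per-event normalized cumulative spike count
#'
#' For sorted event-relative spike times of one condition, the cumulative
#' count of the i-th spike divided by the number of events in that
#' condition: the average number of spikes per event up to each spike time.
#' Normalizing by the event count makes conditions with unequal trial
#' numbers directly comparable.
#'
#' @param v Sorted numeric vector of event-relative spike times.
#' @param n_events Number of events in the condition (>= 1).
#' @return Numeric vector `seq_along(v) / n_events` (empty when `v` is).
#' @export
per_event_cumulative <- function(v, n_events) {
  if (n_events < 1) abort("`n_events` must be at least 1.")
  seq_along(v) / n_events
}

#' Merged time grid of two conditions
#'
#' The sorted union of both conditions' event-relative spike times, with
#' duplicates collapsed to a single grid point.
#'
#' @param v_a,v_b Sorted numeric vectors of event-relative spike times.
#' @return Sorted numeric vector; errors when both inputs are empty.
#' @export
merged_grid <- function(v_a, v_b) {
  if (length(v_a) + length(v_b) == 0L) {
    abort("Cannot build a time grid from two empty spike vectors.")
  }
  sort(unique(c(v_a, v_b)))
}

#' Interpolate a cumulative spike vector onto a time grid
#'
#' Piecewise-linear interpolation of the step-count samples `(v_i, c_i)`
#' evaluated at every grid point, with constant extrapolation: 0 below the
#' first sample and the last cumulative value above the last sample. At a
#' duplicated sample time the upper cumulative value is used.
#'
#' @param v Sorted numeric vector of sample times (may be empty).
#' @param cum Cumulative values at `v`, same length.
#' @param grid Sorted numeric vector of evaluation points.
#' @return Numeric vector of interpolated values, one per grid point.
#' @export
interpolate_cumulative <- function(v, cum, grid) {
  if (length(v) != length(cum)) abort("`v` and `cum` must have equal length.")
  if (length(v) == 0L) return(numeric(length(grid)))
  if (length(v) == 1L) {
    return(ifelse(grid < v, 0, cum))
  }
  approx(v, cum, xout = grid, method = "linear",
         yleft = 0, yright = cum[length(cum)], ties = max)$y
}

#' Detrended difference between two conditions' cumulative spike rates
#'
#' Builds the merged grid, interpolates both per-event cumulative vectors
#' onto it, takes their difference, and removes the straight line through
#' the difference's endpoints. The linear trend corresponds to a constant
#' offset in spiking rates; what remains isolates transient divergence. The
#' detrended difference is exactly zero at the first and last grid points.
#'
#' @param v_a,v_b Sorted numeric vectors of event-relative spike times for
#'   conditions a and b.
#' @param n_events_a,n_events_b Event counts of the two conditions.
#' @return An object of class `difference_trace`: a list with `times` (the
#'   merged grid), `cum_a`, `cum_b` (interpolated spikes-per-event),
#'   `difference`, `baseline` (the linear trend), `deviation` (the
#'   detrended difference) and `mean_deviation`. Errors when the grid has
#'   fewer than two points.
#' @export
difference_trace <- function(v_a, v_b, n_events_a, n_events_b) {
  out <- diff_trace_impl(v_a, v_b, n_events_a, n_events_b)
  if (is.null(out)) {
    abort("Need at least two distinct spike times across conditions.")
  }
  out
}

# Returns NULL (instead of erroring) on a degenerate grid; the permutation
# null uses this to skip vacuous resamples.
diff_trace_impl <- function(v_a, v_b, n_events_a, n_events_b) {
  if (length(v_a) + length(v_b) == 0L) return(NULL)
  grid <- sort(unique(c(v_a, v_b)))
  if (length(grid) < 2L) return(NULL)
  ca <- interpolate_cumulative(v_a, per_event_cumulative(v_a, n_events_a), grid)
  cb <- interpolate_cumulative(v_b, per_event_cumulative(v_b, n_events_b), grid)
  d <- ca - cb
  n <- length(grid)
  # Endpoint-exact form of the linear trend: convex weights guarantee the
  # detrended difference is exactly zero at both ends in floating point.
  wgt <- (grid - grid[1]) / (grid[n] - grid[1])
  base <- (1 - wgt) * d[1] + wgt * d[n]
  dd <- d - base
  structure(
    list(
      times = grid, cum_a = ca, cum_b = cb,
      difference = d, baseline = base,
      deviation = dd, mean_deviation = mean(dd)
    ),
    class = "difference_trace"
  )
}

#' Trial-swap permutation null for the two-sample statistic
#'
#' Pools the per-event aligned spike sets of both conditions and, per
#' resample, draws `n_events_a` sets without replacement as pseudo-condition
#' a, assigning the complement to pseudo-condition b (a permutation split
#' that preserves total spike mass). The detrended-difference extremal is
#' recomputed on each split and mean-normalized exactly as for the observed
#' data.
#'
#' @param pooled List of per-event aligned spike-time vectors from both
#'   conditions (length `n_events_a + n_events_b`); see
#'   [align_spikes_by_event()].
#' @param n_events_a,n_events_b Event counts of the two conditions.
#' @param n_resamples Number of permutation resamples (default 250).
#' @param seed Optional integer base seed; per-resample streams are derived
#'   by counter as in [jitter_null()].
#' @return Numeric vector of `n_resamples` non-negative null statistics.
#' @export
shuffle_null <- function(pooled, n_events_a, n_events_b,
                         n_resamples = 250, seed = NULL) {
  n_sets <- length(pooled)
  if (n_events_a + n_events_b < 2) abort("Need at least two events in total.")
  if (n_sets != n_events_a + n_events_b) {
    abort("`pooled` must have one spike set per event across both conditions.")
  }
  vapply(seq_len(n_resamples), function(m) {
    if (!is.null(seed)) set.seed(counter_seed(seed, m))
    pick <- sample.int(n_sets, n_events_a)
    va <- sort(unlist(pooled[pick], use.names = FALSE))
    vb <- sort(unlist(pooled[-pick], use.names = FALSE))
    tr <- diff_trace_impl(va, vb, n_events_a, n_events_b)
    if (is.null(tr)) return(0)
    abs(extremal_deviation(tr)$value - tr$mean_deviation)
  }, numeric(1))
}

#' Estimate the onset of condition-specific spiking divergence (two-sample)
#'
#' Estimates the earliest time at which spiking rates diverge significantly
#' between two conditions sharing the same analysis window. Each iteration
#' stitches spikes against the merged event sequence of both conditions (so
#' shared time is excised identically), builds the detrended difference of
#' per-event-normalized cumulative spike counts, tests its mean-normalized
#' extremal against a trial-swap permutation null, and narrows the window's
#' upper bound to the extremal time while significant. The estimate is the
#' extremal time of the last significant iteration; undefined when the
#' first iteration is non-significant.
#'
#' @param spikes Numeric vector of spike times in seconds, or a data frame
#'   with a `spike_time_s` column.
#' @param events_a Event times of condition a (numeric vector or data
#'   frame), or a data frame with `event_time_s` and `condition` columns
#'   covering both conditions (then leave `events_b` as `NULL` and
#'   optionally name the two levels with `cond_a` / `cond_b`).
#' @param events_b Event times of condition b, or `NULL` when `events_a`
#'   carries a `condition` column.
#' @param t0,t1 Shared analysis window in seconds relative to each event.
#' @param alpha Significance threshold (default 0.05).
#' @param n_resamples Number of trial-swap resamples per iteration
#'   (default 250).
#' @param p_method `"gumbel"` (default) or `"empirical"`.
#' @param cond_a,cond_b Condition labels to use when `events_a` is a
#'   two-condition data frame; default the first two distinct labels.
#' @param min_spikes Minimum pooled event-relative spike count to attempt an
#'   iteration (default 3).
#' @param seed Optional integer seed (counter-derived resample streams).
#'
#' @return An object of class `latenzy2_fit`, structured like
#'   [latenzy()]'s result, with `traces` holding the per-iteration
#'   detrended-difference curves. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#'
#' @examples
#' sim <- simulate_two_condition(n_events_a = 60, n_events_b = 60, seed = 1)
#' fit <- latenzy2(sim$spikes, sim$events_a, sim$events_b,
#'                 t0 = -0.1, t1 = 1, n_resamples = 100, seed = 1)
#' fit
#' @export
latenzy2 <- function(spikes, events_a, events_b = NULL, t0, t1,
                     alpha = 0.05, n_resamples = 250,
                     p_method = c("gumbel", "empirical"),
                     cond_a = NULL, cond_b = NULL,
                     min_spikes = 3, seed = NULL) {
  p_method <- match.arg(p_method)
  spikes <- as_spike_times(spikes)
  if (is.null(events_b)) {
    split <- split_condition_events(events_a, cond_a, cond_b)
    wa <- split$a
    wb <- split$b
  } else {
    wa <- as_event_times(events_a, "events_a")
    wb <- as_event_times(events_b, "events_b")
  }
  check_window(t0, t1, initial = TRUE)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  qa <- length(wa)
  qb <- length(wb)

  # Merged event sequence with condition labels, kept sorted in time so
  # stitching removes the same epochs for both conditions.
  ev <- c(wa, wb)
  lab <- rep(c("a", "b"), c(qa, qb))
  o <- order(ev)
  ev <- ev[o]
  lab <- lab[o]

  with_seed(seed, {
    t1_cur <- t1
    latency <- NA_real_
    defined <- FALSE
    rows <- list()
    traces <- list()
    l <- 0L
    repeat {
      l <- l + 1L
      st <- stitch_spikes(spikes, ev, t0, t1_cur)
      sets <- align_spikes_by_event(st$spikes, st$events, t0, t1_cur)
      va <- sort(unlist(sets[lab == "a"], use.names = FALSE))
      vb <- sort(unlist(sets[lab == "b"], use.names = FALSE))
      if (length(va) + length(vb) < min_spikes) break
      tr <- diff_trace_impl(va, vb, qa, qb)
      if (is.null(tr)) break
      ex <- extremal_deviation(tr)
      zr <- normalize_statistic(ex$value, tr$mean_deviation)
      null <- shuffle_null(sets, qa, qb, n_resamples = n_resamples,
                           seed = iteration_seed(seed, l))
      test <- if (p_method == "gumbel") gumbel_p(zr, null) else empirical_p(zr, null)
      sig <- test$p_value < alpha
      rows[[l]] <- tibble(
        iteration = l, t0 = t0, t1 = t1_cur,
        n_spikes_a = length(va), n_spikes_b = length(vb),
        zeta = ex$value, zeta_norm = zr, tau_zeta = ex$time,
        p_value = test$p_value, significant = sig
      )
      traces[[l]] <- list(times = tr$times, deviation = tr$deviation)
      if (!sig) break
      tau <- ex$time
      latency <- tau
      defined <- TRUE
      if (tau >= t1_cur || tau <= t0) break
      t1_cur <- tau
    }
    structure(
      list(
        latency = latency,
        defined = defined,
        iterations = if (length(rows)) bind_rows(rows) else empty_iteration2_tbl(),
        traces = traces,
        n_events = c(a = qa, b = qb),
        alpha = alpha, n_resamples = n_resamples, p_method = p_method,
        window = c(t0 = t0, t1 = t1), seed = seed
      ),
      class = "latenzy2_fit"
    )
  })
}

empty_iteration2_tbl <- function() {
  tibble(
    iteration = integer(), t0 = double(), t1 = double(),
    n_spikes_a = integer(), n_spikes_b = integer(),
    zeta = double(), zeta_norm = double(), tau_zeta = double(),
    p_value = double(), significant = logical()
  )
}

split_condition_events <- function(events, cond_a, cond_b) {
  if (!is.data.frame(events) || !all(c("event_time_s", "condition") %in% names(events))) {
    abort(paste0(
      "When `events_b` is NULL, `events_a` must be a data frame with ",
      "`event_time_s` and `condition` columns."
    ))
  }
  levels <- unique(as.character(events$condition))
  cond_a <- cond_a %||% levels[1]
  cond_b <- cond_b %||% setdiff(levels, cond_a)[1]
  if (is.na(cond_b) || !all(c(cond_a, cond_b) %in% levels)) {
    abort("Could not find two condition labels in `events$condition`.")
  }
  list(
    a = as_event_times(events$event_time_s[events$condition == cond_a], "events_a"),
    b = as_event_times(events$event_time_s[events$condition == cond_b], "events_b")
  )
}

#' @export
print.latenzy2_fit <- function(x, ...) {
  cat("Binning-free divergence latency estimate (two conditions)\n")
  if (x$defined) {
    cat(sprintf("  divergence latency: %.4f s\n", x$latency))
  } else {
    cat("  divergence latency: undefined (no significant condition difference)\n")
  }
  cat(sprintf("  events: %d vs %d; window [%.3f, %.3f] s, alpha = %g, %d resamples (%s p-values)\n",
              x$n_events[["a"]], x$n_events[["b"]],
              x$window[["t0"]], x$window[["t1"]], x$alpha, x$n_resamples, x$p_method))
  cat(sprintf("  iterations: %d\n", nrow(x$iterations)))
  invisible(x)
}
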