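# Cumulative-fraction statistics: the deviation of the pooled spike-time CDF
# from the linear baseline expected under temporally unmodulated spiking.

#' Fractional positions of sorted spike times
#'
#' For `n` pooled event-relative spike times, the fractional position of the
#' i-th spike is `i / n`: the empirical cumulative density of spikes sampled
#' at the spike times themselves.
#'
#' @param v Sorted numeric vector of spike times; must be non-empty (callers
#'   add boundary spikes first, so `n >= 2` in practice).
#' @return Numeric vector `seq_len(n) / n`.
#' @export
fractional_positions <- function(v) {
  n <- length(v)
  if (n < 1L) abort("`v` must contain at least one spike time.")
  seq_len(n) / n
}

#' Linear baseline density
#'
#' Under the null hypothesis of no time-locked modulation, the pooled
#' spike-time CDF converges to a straight line as the number of events grows;
#' its value at time `v` is `(v - t0) / (t1 - t0)`.
#'
#' @param v Numeric vector of spike times in `[t0, t1]`.
#' @param t0,t1 Window bounds in seconds.
#' @return Numeric vector of baseline fractions in `[0, 1]`.
#' @export
linear_baseline <- function(v, t0, t1) {
  check_window(t0, t1, initial = FALSE)
  (v - t0) / (t1 - t0)
}

#' Build a deviation trace
#'
#' Combines [fractional_positions()] and [linear_baseline()] into the
#' deviation vector whose extremal value is the test statistic: at each spike
#' time, the difference between the empirical cumulative fraction and the
#' linear baseline. With boundary spikes included, the deviation at the last
#' element is exactly zero.
#'
#' @param v Sorted numeric vector of event-relative spike times, boundary
#'   spikes included (see [add_boundary_spikes()]).
#' @param t0,t1 Window bounds in seconds.
#' @return An object of class `deviation_trace`: a list with `times`,
#'   `fractions`, `baseline`, `deviation` and `mean_deviation`.
#' @export
deviation_trace <- function(v, t0, t1) {
  g <- fractional_positions(v)
  b <- linear_baseline(v, t0, t1)
  d <- g - b
  structure(
    list(
      times = v, fractions = g, baseline = b,
      deviation = d, mean_deviation = mean(d)
    ),
    class = "deviation_trace"
  )
}

#' Extremal deviation and its latency
#'
#' Extracts the extremal value of a deviation vector: the minimum when
#' `|min| >= |max|` (ties go to the minimum), the maximum otherwise. The
#' associated latency is the spike (or grid) time at the arg-extremum;
#' arg-extremum ties resolve to the earliest index.
#'
#' @param trace A [deviation_trace()] or [difference_trace()] object, or any
#'   list with numeric fields `deviation` and `times` of equal length.
#' @return A list with `value` (signed extremal deviation), `time` (seconds)
#'   and `index` (position in `times`).
#' @export
extremal_deviation <- function(trace) {
  d <- trace$deviation
  if (length(d) < 1L) abort("Deviation vector must be non-empty.")
  mn <- min(d)
  mx <- max(d)
  if (abs(mn) >= abs(mx)) {
    i <- which.min(d)
    val <- mn
  } else {
    i <- which.max(d)
    val <- mx
  }
  list(value = val, time = trace$times[[i]], index = i)
}

#' @export
print.deviation_trace <- function(x, ...) {
  cat(sprintf(
    "<deviation_trace> %d spike times in [%.4g, %.4g] s; extremal deviation %.4g\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    extremal_deviation(x)$value
  ))
  invisible(x)
}
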