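# Null distributions of the extremal deviation and their conversion to
# p-values, either through a moment-fitted Gumbel extreme-value law or an
# empirical quantile.

#' Jitter event times uniformly
#'
#' Shifts each event time by an independent draw from Uniform(-T, T), where T
#' is the analysis-window duration, and re-sorts. Jittered events are not
#' clipped to the recording. This destroys time-locking while preserving the
#' event count and the overall temporal structure of the session.
#'
#' @param events Numeric vector of event times in seconds.
#' @param window_duration Window duration T in seconds; must be positive.
#' @return Sorted numeric vector of jittered event times.
#' @export
jitter_events <- function(events, window_duration) {
  events <- as_event_times(events)
  if (!is.finite(window_duration) || window_duration <= 0) {
    abort("`window_duration` must be a positive number.")
  }
  sort(events + runif(length(events), -window_duration, window_duration))
}

#' Jitter null distribution of the normalized extremal deviation
#'
#' Repeats the deviation computation `n_resamples` times with jittered event
#' times: per resample, events are jittered within +/- the window duration,
#' spikes are aligned to the jittered events (half-open windows), boundary
#' spikes are added, and the mean-normalized absolute extremal deviation
#' `|zeta'(m) - mean(delta'(m))|` is recorded.
#'
#' The inputs must already be stitched for the current analysis window;
#' stitching is applied once per estimator iteration on the real data, not
#' inside the null loop, so both the observed and resampled statistics see
#' the same temporal segments.
#'
#' @param spikes Stitched spike times (numeric vector, seconds).
#' @param events Stitched event times (numeric vector, seconds).
#' @param t0,t1 Current analysis window bounds in seconds.
#' @param n_resamples Number of jitter resamples M (default 100); at least 2.
#' @param seed Optional integer base seed; resample `m` uses a seed derived
#'   from `seed + m`, so results are reproducible and extending
#'   `n_resamples` does not perturb earlier draws. `NULL` draws from the
#'   current RNG stream.
#' @return Numeric vector of `n_resamples` non-negative null statistics.
#' @export
jitter_null <- function(spikes, events, t0, t1, n_resamples = 100, seed = NULL) {
  spikes <- as_spike_times(spikes)
  events <- as_event_times(events)
  check_window(t0, t1, initial = FALSE)
  if (n_resamples < 2) abort("`n_resamples` must be at least 2.")
  dur <- t1 - t0
  vapply(seq_len(n_resamples), function(m) {
    if (!is.null(seed)) set.seed(counter_seed(seed, m))
    w <- sort(events + runif(length(events), -dur, dur))
    v <- align_spikes(spikes, w, t0, t1)
    tr <- deviation_trace(add_boundary_spikes(v, t0, t1), t0, t1)
    abs(extremal_deviation(tr)$value - tr$mean_deviation)
  }, numeric(1))
}

#' Mean-normalized deviation statistic
#'
#' The test statistic compared against the null distribution:
#' `|zeta - mean(delta)|`, the absolute difference between the signed
#' extremal deviation and the mean of its own deviation vector.
#'
#' @param value Signed extremal deviation (see [extremal_deviation()]).
#' @param mean_deviation Mean of the deviation vector it came from.
#' @return Non-negative scalar.
#' @export
normalize_statistic <- function(value, mean_deviation) {
  abs(value - mean_deviation)
}

#' Gumbel-approximated p-value
#'
#' Fits a Gumbel extreme-value law to the null samples by the method of
#' moments (`beta = sqrt(6 * var) / pi`, `mu = mean - gamma * beta` with
#' gamma the Euler-Mascheroni constant) and returns the upper-tail
#' probability `p = 1 - exp(-exp(-(statistic - mu) / beta))`. Falls back to
#' [empirical_p()] when the null samples have zero variance.
#'
#' @param statistic Observed mean-normalized statistic.
#' @param null Numeric vector of null samples (length >= 2).
#' @return A list with `statistic`, `p_value`, `method` (`"gumbel"`, or
#'   `"empirical"` after a degenerate-null fallback), and for the Gumbel
#'   route `location` and `scale`.
#' @examples
#' gumbel_p(3, c(1, 2, 3))
#' @export
gumbel_p <- function(statistic, null) {
  if (length(null) < 2L) abort("Gumbel fit needs at least 2 null samples.")
  v <- var(null)
  if (v == 0) {
    res <- empirical_p(statistic, null)
    res$degenerate_null <- TRUE
    return(res)
  }
  euler_gamma <- 0.57721566490153286
  beta <- sqrt(6 * v) / pi
  mu <- mean(null) - euler_gamma * beta
  p <- -expm1(-exp(-(statistic - mu) / beta)) # 1 - exp(.), precise in the tail
  list(statistic = statistic, p_value = p, method = "gumbel",
       location = mu, scale = beta)
}

#' Empirical (quantile-position) p-value
#'
#' The add-one permutation estimator of the upper-tail probability:
#' `p = (1 + #{null >= statistic}) / (M + 1)`. Never exactly zero.
#'
#' @inheritParams gumbel_p
#' @return A list with `statistic`, `p_value` and `method = "empirical"`.
#' @export
empirical_p <- function(statistic, null) {
  if (length(null) < 1L) abort("Need at least one null sample.")
  p <- (1 + sum(null >= statistic)) / (length(null) + 1)
  list(statistic = statistic, p_value = p, method = "empirical")
}
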