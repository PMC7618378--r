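# Seeded generators of trial-locked inhomogeneous-Poisson spike trains with
# known ground-truth onsets, so every estimator can be exercised and
# calibrated without recorded data.

#' Sample an (in)homogeneous Poisson spike train by thinning
#'
#' Lewis-Shedler-style thinning: candidate spikes are drawn from a
#' homogeneous Poisson process at `peak_rate` over `[0, duration)` and each
#' is accepted with probability `rate(t) / peak_rate`. Exact for any bounded
#' rate function.
#'
#' @param rate A vectorized function of time (seconds) returning the
#'   instantaneous rate in spikes/second, or a single non-negative number
#'   for a homogeneous process.
#' @param duration Duration of the realization in seconds.
#' @param peak_rate Upper bound of the rate function (defaults to `rate`
#'   itself when `rate` is a constant). Rate evaluations must lie in
#'   `[0, peak_rate]`.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times in `[0, duration)`.
#' @examples
#' simulate_poisson_spikes(10, duration = 5, seed = 1)
#' @export
simulate_poisson_spikes <- function(rate, duration, peak_rate = NULL, seed = NULL) {
  if (is.numeric(rate) && length(rate) == 1L) {
    const <- rate
    if (const < 0) abort("`rate` must be non-negative.")
    peak_rate <- peak_rate %||% const
    rate <- function(t) rep(const, length(t))
  }
  if (is.null(peak_rate)) abort("`peak_rate` is required when `rate` is a function.")
  if (!is.finite(peak_rate) || peak_rate < 0) abort("`peak_rate` must be finite and non-negative.")
  with_seed(seed, {
    if (peak_rate == 0 || duration <= 0) return(numeric(0))
    n_cand <- rpois(1, peak_rate * duration)
    if (n_cand == 0) return(numeric(0))
    t_cand <- sort(runif(n_cand, 0, duration))
    lambda <- rate(t_cand)
    if (any(lambda < 0)) abort("Rate function returned a negative value.")
    if (any(lambda > peak_rate * (1 + 1e-12))) {
      abort("Rate function exceeds `peak_rate`; thinning would be biased.")
    }
    t_cand[runif(n_cand) < lambda / peak_rate]
  })
}

#' Simulate a step-response session with known onset
#'
#' Generates a session of trial-locked spiking: events at regular intervals,
#' baseline Poisson firing everywhere, and - with probability
#' `response_probability` per event (the response consistency) - a step from
#' `baseline_rate` to `response_rate` starting `onset` seconds after the
#' event and lasting `response_duration` seconds. Ground truth is the onset.
#'
#' @param n_events Number of events (trials).
#' @param baseline_rate Baseline rate in spikes/second.
#' @param response_rate Rate during the response step in spikes/second.
#' @param onset Response onset relative to the event, in seconds.
#' @param response_duration Duration of the step in seconds.
#' @param inter_event_interval Spacing between events in seconds.
#' @param response_probability Probability that an event elicits the step
#'   (default 1).
#' @param pre_time Session time before the first event in seconds (default
#'   one inter-event interval, leaving room for pre-event analysis windows).
#' @param seed Optional integer seed; realizations are reproducible
#'   bit-exactly from the parameters and seed.
#' @return An object of class `spike_sim`: a list with `spikes` (sorted
#'   numeric vector), `events` (numeric vector), `true_onset` (seconds) and
#'   `params` (echo of all generator settings).
#' @examples
#' sim <- simulate_step_response(n_events = 50, seed = 1)
#' length(sim$spikes)
#' @export
simulate_step_response <- function(n_events = 100,
                                   baseline_rate = 5,
                                   response_rate = 40,
                                   onset = 0.1,
                                   response_duration = 0.5,
                                   inter_event_interval = 1.5,
                                   response_probability = 1,
                                   pre_time = inter_event_interval,
                                   seed = NULL) {
  if (baseline_rate < 0 || response_rate < 0) abort("Rates must be non-negative.")
  if (response_probability < 0 || response_probability > 1) {
    abort("`response_probability` must be in [0, 1].")
  }
  events <- pre_time + inter_event_interval * (seq_len(n_events) - 1)
  duration <- pre_time + inter_event_interval * n_events
  with_seed(seed, {
    responding <- runif(n_events) < response_probability
    rate_fn <- function(t) {
      k <- findInterval(t, events)
      rel <- t - events[pmax(k, 1L)]
      in_step <- k >= 1L & responding[pmax(k, 1L)] &
        rel >= onset & rel < onset + response_duration
      ifelse(in_step, response_rate, baseline_rate)
    }
    spikes <- simulate_poisson_spikes(rate_fn, duration,
                                      peak_rate = max(baseline_rate, response_rate))
    structure(
      list(
        spikes = spikes,
        events = events,
        true_onset = onset,
        params = list(
          n_events = n_events, baseline_rate = baseline_rate,
          response_rate = response_rate, onset = onset,
          response_duration = response_duration,
          inter_event_interval = inter_event_interval,
          response_probability = response_probability,
          pre_time = pre_time, seed = seed
        )
      ),
      class = "spike_sim"
    )
  })
}

#' Simulate a two-condition session with a known divergence time
#'
#' Generates trial-locked spiking for two interleaved conditions whose rate
#' functions are identical up to `divergence_time` - baseline before the
#' event, a shared onset transient, then a shared sustained rate - and
#' differ only in sustained rate afterwards. Ground truth is the divergence
#' time.
#'
#' The per-event rate profile is: `baseline_rate` before the event and after
#' `response_end`; `transient_rate` on `[0, transient_duration)`;
#' `sustained_b` (the shared sustained level) on
#' `[transient_duration, divergence_time)`; then `sustained_a` versus
#' `sustained_b` on `[divergence_time, response_end)`. Setting
#' `sustained_a = sustained_b` yields exchangeable conditions.
#'
#' @param n_events_a,n_events_b Trials per condition.
#' @param baseline_rate Pre-event rate in spikes/second.
#' @param transient_rate Rate of the shared onset transient in
#'   spikes/second.
#' @param transient_duration Duration of the transient in seconds.
#' @param sustained_a,sustained_b Sustained rates of the two conditions
#'   after `divergence_time`, in spikes/second.
#' @param divergence_time Time after the event at which the conditions'
#'   rates separate, in seconds; must not precede the transient's end.
#' @param response_end End of the sustained response relative to the event,
#'   in seconds.
#' @param inter_event_interval Spacing between successive events in seconds.
#' @param pre_time Session time before the first event in seconds.
#' @param seed Optional integer seed.
#' @return An object of class `spike_sim`: a list with `spikes`, `events`
#'   (all events, sorted), `condition` (label per event), convenience
#'   vectors `events_a` / `events_b`, `true_divergence` (seconds) and
#'   `params`.
#' @examples
#' sim <- simulate_two_condition(n_events_a = 30, n_events_b = 30, seed = 1)
#' table(sim$condition)
#' @export
simulate_two_condition <- function(n_events_a = 150, n_events_b = 150,
                                   baseline_rate = 5,
                                   transient_rate = 50,
                                   transient_duration = 0.1,
                                   sustained_a = 20, sustained_b = 10,
                                   divergence_time = 0.15,
                                   response_end = 1.0,
                                   inter_event_interval = 1.5,
                                   pre_time = inter_event_interval,
                                   seed = NULL) {
  rates <- c(baseline_rate, transient_rate, sustained_a, sustained_b)
  if (any(rates < 0)) abort("Rates must be non-negative.")
  if (divergence_time < transient_duration) {
    abort("`divergence_time` must not precede the end of the shared transient.")
  }
  n_total <- n_events_a + n_events_b
  events <- pre_time + inter_event_interval * (seq_len(n_total) - 1)
  duration <- pre_time + inter_event_interval * n_total
  with_seed(seed, {
    condition <- sample(rep(c("a", "b"), c(n_events_a, n_events_b)))
    is_a <- condition == "a"
    cond_profile <- function(rel, a_like) {
      sustained <- ifelse(a_like, sustained_a, sustained_b)
      out <- rep(baseline_rate, length(rel))
      out[rel >= 0 & rel < transient_duration] <- transient_rate
      shared <- rel >= transient_duration & rel < divergence_time
      out[shared] <- sustained_b
      diverged <- rel >= divergence_time & rel < response_end
      out[diverged] <- sustained[diverged]
      out
    }
    rate_fn <- function(t) {
      k <- findInterval(t, events)
      kk <- pmax(k, 1L)
      rel <- t - events[kk]
      out <- cond_profile(rel, is_a[kk])
      out[k < 1L] <- baseline_rate
      out
    }
    spikes <- simulate_poisson_spikes(rate_fn, duration, peak_rate = max(rates))
    structure(
      list(
        spikes = spikes,
        events = events,
        condition = condition,
        events_a = events[is_a],
        events_b = events[!is_a],
        true_divergence = divergence_time,
        params = list(
          n_events_a = n_events_a, n_events_b = n_events_b,
          baseline_rate = baseline_rate, transient_rate = transient_rate,
          transient_duration = transient_duration,
          sustained_a = sustained_a, sustained_b = sustained_b,
          divergence_time = divergence_time, response_end = response_end,
          inter_event_interval = inter_event_interval,
          pre_time = pre_time, seed = seed
        )
      ),
      class = "spike_sim"
    )
  })
}

#' @export
print.spike_sim <- function(x, ...) {
  truth <- if (!is.null(x$true_onset)) {
    sprintf("true onset %.3f s", x$true_onset)
  } else {
    sprintf("true divergence %.3f s", x$true_divergence)
  }
  cat(sprintf("<spike_sim> %d spikes, %d events, %s\n",
              length(x$spikes), length(x$events), truth))
  invisible(x)
}
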