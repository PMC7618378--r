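# broom-style tidiers for the fitted objects.

#' Tidy the per-iteration table of a latency fit
#'
#' @param x A `latenzy_fit` or `latenzy2_fit`.
#' @param ... Unused.
#' @return A tibble with one row per refinement iteration.
#' @method tidy latenzy_fit
#' @export
tidy.latenzy_fit <- function(x, ...) {
  x$iterations
}

#' @method tidy latenzy2_fit
#' @export
tidy.latenzy2_fit <- function(x, ...) {
  x$iterations
}

#' One-row summary of a latency fit
#'
#' @param x A `latenzy_fit` or `latenzy2_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the latency estimate, whether it is
#'   defined, the iteration count, the first iteration's p-value and the
#'   settings.
#' @method glance latenzy_fit
#' @export
glance.latenzy_fit <- function(x, ...) {
  tibble(
    latency_s = x$latency,
    defined = x$defined,
    n_iterations = nrow(x$iterations),
    p_first = if (nrow(x$iterations)) x$iterations$p_value[1] else NA_real_,
    alpha = x$alpha,
    n_resamples = x$n_resamples,
    p_method = x$p_method
  )
}

#' @method glance latenzy2_fit
#' @export
glance.latenzy2_fit <- function(x, ...) {
  out <- glance.latenzy_fit(x, ...)
  out$n_events_a <- x$n_events[["a"]]
  out$n_events_b <- x$n_events[["b"]]
  out
}

#' Tidy a PETH into a long table
#'
#' @param x A [build_peth()] object.
#' @param ... Unused.
#' @return A tibble with `center` (seconds) and `rate` (spikes/s) per bin.
#' @method tidy peth
#' @export
tidy.peth <- function(x, ...) {
  tibble(center = x$centers, rate = x$rates)
}

#' Tidy / summarise a power curve
#'
#' @param x A [power_analysis()] object.
#' @param ... Unused.
#' @return `tidy()`: the per-size power table; `glance()`: a one-row
#'   summary including the smallest sufficient sample size.
#' @method tidy power_curve
#' @export
tidy.power_curve <- function(x, ...) {
  x$curve
}

#' @rdname tidy.power_curve
#' @method glance power_curve
#' @export
glance.power_curve <- function(x, ...) {
  tibble(
    n_sufficient = x$n_sufficient,
    test = x$test,
    n_sim = x$n_sim,
    alpha = x$alpha,
    power_goal = x$power_goal,
    max_power = max(x$curve$power)
  )
}
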