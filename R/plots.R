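# Diagnostic figures: deviation traces with the latency estimate, PETHs,
# rasters and power curves.

#' @import ggplot2
NULL

trace_tbl <- function(x) {
  bind_rows(lapply(seq_along(x$traces), function(l) {
    tibble(iteration = l,
           time_s = x$traces[[l]]$times,
           deviation = x$traces[[l]]$deviation)
  }))
}

#' Plot the deviation traces of a latency fit
#'
#' One cumulative-deviation curve per refinement iteration, with the final
#' latency estimate marked when defined.
#'
#' @param object A `latenzy_fit` or `latenzy2_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latenzy_fit
#' @export
autoplot.latenzy_fit <- function(object, ...) {
  df <- trace_tbl(object)
  p <- ggplot(df, aes(x = .data$time_s, y = .data$deviation,
                      group = .data$iteration,
                      colour = factor(.data$iteration))) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    labs(x = "Time from event (s)",
         y = "Deviation from linear baseline",
         colour = "Iteration") +
    theme_minimal()
  if (isTRUE(object$defined)) {
    p <- p + geom_vline(xintercept = object$latency,
                        colour = "red", linetype = "dashed")
  }
  p
}

#' @method autoplot latenzy2_fit
#' @export
autoplot.latenzy2_fit <- function(object, ...) {
  autoplot.latenzy_fit(object, ...) +
    labs(y = "Detrended cumulative-rate difference (spikes/event)")
}

#' Plot a PETH
#'
#' @param object A [build_peth()] object.
#' @param ... Unused.
#' @return A ggplot object (step plot of rate against bin center).
#' @method autoplot peth
#' @export
autoplot.peth <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$center, y = .data$rate)) +
    geom_step() +
    geom_vline(xintercept = 0, colour = "grey60", linetype = "dotted") +
    labs(x = "Time from event (s)", y = "Rate (spikes/s)") +
    theme_minimal()
}

#' Plot a Monte Carlo power curve
#'
#' @param object A [power_analysis()] object.
#' @param ... Unused.
#' @return A ggplot object with the power goal marked.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$sample_size, y = .data$power)) +
    geom_hline(yintercept = object$power_goal, colour = "grey60",
               linetype = "dashed") +
    geom_line() +
    geom_point() +
    ylim(0, 1) +
    labs(x = "Sample size per group", y = "Power") +
    theme_minimal()
}

#' Raster plot of event-aligned spikes
#'
#' @inheritParams stitch_spikes
#' @return A ggplot object with one row per event.
#' @export
plot_raster <- function(spikes, events, t0, t1) {
  events <- as_event_times(events)
  sets <- align_spikes_by_event(spikes, events, t0, t1)
  df <- bind_rows(lapply(seq_along(sets), function(k) {
    tibble(event = k, time_s = sets[[k]])
  }))
  ggplot(df, aes(x = .data$time_s, y = .data$event)) +
    geom_point(shape = "|", size = 2) +
    geom_vline(xintercept = 0, colour = "red", linetype = "dotted") +
    labs(x = "Time from event (s)", y = "Event") +
    theme_minimal()
}
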