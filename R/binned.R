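# Bin-based comparator methods: peri-event time histograms and the half-max
# and SD-threshold latency rules that operate on them.

#' Build a peri-event time histogram (PETH)
#'
#' Counts event-relative spikes in uniform bins tiling `[t0, t1]` and
#' divides by `n_events * bin_width` to obtain a trial-averaged rate in
#' spikes/second. A partial terminal bin is dropped rather than rescaled, so
#' every bin has identical duration.
#'
#' @inheritParams stitch_spikes
#' @param bin_width Bin width in seconds; must be positive and smaller than
#'   the window duration.
#' @return An object of class `peth`: a list with `bin_edges`, `centers`,
#'   `rates` (spikes/s), `bin_width` and `n_events`.
#' @export
build_peth <- function(spikes, events, t0, t1, bin_width) {
  events <- as_event_times(events)
  check_window(t0, t1, initial = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0) abort("`bin_width` must be positive.")
  if (bin_width >= t1 - t0) abort("`bin_width` must be smaller than the window duration.")
  n_bins <- floor((t1 - t0) / bin_width + 1e-9)
  edges <- t0 + bin_width * (0:n_bins)
  v <- align_spikes(spikes, events, t0, t1)
  # Right-closed bins (lo, hi], matching the window membership convention.
  bin <- findInterval(v, edges, left.open = TRUE)
  counts <- tabulate(bin[bin >= 1L & bin <= n_bins], nbins = n_bins)
  structure(
    list(
      bin_edges = edges,
      centers = edges[-1] - bin_width / 2,
      rates = counts / (length(events) * bin_width),
      bin_width = bin_width,
      n_events = length(events)
    ),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d bins of %.4g ms over [%.3g, %.3g] s, %d events\n",
              length(x$rates), 1000 * x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)], x$n_events))
  invisible(x)
}

# Mean rate over baseline bins (bin centers before the event).
peth_baseline <- function(peth) {
  base <- peth$centers < 0
  if (!any(base)) abort("PETH has no baseline bins (centers before 0).")
  base
}

#' Half-max latency from a PETH
#'
#' The latency is the center of the first post-onset bin (center > 0) whose
#' rate deviates from the baseline mean by more than half the peak absolute
#' deviation, where the peak is searched over all bins. Responses in either
#' direction (excitation or suppression) are detected through the absolute
#' value. Returns `NA` when no bin qualifies (including flat PETHs).
#'
#' @param peth A [build_peth()] object with at least one baseline and one
#'   post-onset bin.
#' @return Latency in seconds (a bin center), or `NA_real_`.
#' @export
half_max_latency <- function(peth) {
  base <- peth_baseline(peth)
  lambda_b <- mean(peth$rates[base])
  dev <- abs(peth$rates - lambda_b)
  lambda_p <- max(dev)
  post <- which(peth$centers > 0)
  if (!length(post)) abort("PETH has no post-onset bins.")
  hit <- post[dev[post] > lambda_p / 2]
  if (!length(hit)) return(NA_real_)
  peth$centers[hit[1]]
}

#' SD-threshold latency from a PETH
#'
#' The latency is the center of the first post-onset bin whose rate deviates
#' from the baseline mean by more than `k` standard deviations, where the SD
#' is the sample standard deviation across baseline bins of the
#' trial-averaged PETH (temporal variability, not trial-to-trial
#' variability). The default `k = 2.58` is the two-tailed standard-normal
#' critical value at significance 0.01. Returns `NA` when no bin qualifies;
#' a zero baseline SD makes the threshold vacuous and also yields `NA`
#' (with a `degenerate_baseline` attribute).
#'
#' @param peth A [build_peth()] object with at least two baseline bins.
#' @param k Threshold multiplier (default 2.58).
#' @return Latency in seconds (a bin center), or `NA_real_`.
#' @export
sd_threshold_latency <- function(peth, k = 2.58) {
  base <- peth_baseline(peth)
  if (sum(base) < 2L) abort("SD-threshold latency needs at least 2 baseline bins.")
  lambda_b <- mean(peth$rates[base])
  sigma_b <- sd(peth$rates[base])
  post <- which(peth$centers > 0)
  if (!length(post)) abort("PETH has no post-onset bins.")
  if (sigma_b == 0) {
    out <- NA_real_
    attr(out, "degenerate_baseline") <- TRUE
    return(out)
  }
  dev <- abs(peth$rates - lambda_b)
  hit <- post[dev[post] > k * sigma_b]
  if (!length(hit)) return(NA_real_)
  peth$centers[hit[1]]
}

#' Binwise difference between two condition PETHs
#'
#' Subtracts the rates of `peth_b` from `peth_a` bin by bin; the bin grids
#' must be identical. The difference PETH (which may be negative) is the
#' input for bin-based divergence-latency estimation, with downstream rules
#' operating on absolute deviations.
#'
#' @param peth_a,peth_b [build_peth()] objects with identical bin edges.
#' @return A `peth` object whose `rates` are `peth_a$rates - peth_b$rates`
#'   and whose `n_events` is the sum of the inputs'.
#' @export
difference_peth <- function(peth_a, peth_b) {
  if (length(peth_a$bin_edges) != length(peth_b$bin_edges) ||
      !isTRUE(all.equal(peth_a$bin_edges, peth_b$bin_edges))) {
    abort("PETHs must share identical bin edges.")
  }
  out <- peth_a
  out$rates <- peth_a$rates - peth_b$rates
  out$n_events <- peth_a$n_events + peth_b$n_events
  out
}

#' Standard grid of PETH bin widths
#'
#' Eleven logarithmically spaced bin widths from 0.5 ms to 50 ms, the range
#' over which the bin-based comparator methods are evaluated.
#'
#' @return Numeric vector of 11 strictly increasing bin widths in seconds.
#' @export
bin_width_grid <- function() {
  exp(seq(log(5e-4), log(5e-2), length.out = 11))
}
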