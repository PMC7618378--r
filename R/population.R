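# Population-level benchmark statistics: ordinal scores over latency sets,
# trial-subsampling variability, paired bootstrap tests, and Monte Carlo
# power analysis.

#' Monotonicity score of an ordered latency vector
#'
#' Mean sign of successive differences of latencies ordered by an external
#' covariate (for example stimulus contrast): -1 for a strictly decreasing
#' sequence, +1 for strictly increasing, 0 for no consistent trend. Ties
#' contribute 0.
#'
#' @param latencies Numeric vector of finite latencies (length >= 2),
#'   ordered by the covariate.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' monotonicity_score(c(5, 4, 3, 2, 1))
#' @export
monotonicity_score <- function(latencies) {
  if (length(latencies) < 2L) abort("Need at least two latencies.")
  if (anyNA(latencies)) abort("Latencies must be finite (drop undefined estimates first).")
  mean(sign(diff(latencies)))
}

#' Latency dominance score between two sets of latencies
#'
#' Normalized balance of pairwise comparisons:
#' `(#\{a_i > b_j\} - #\{a_i < b_j\}) / (n * m)`, with ties contributing
#' zero. The score is +1 when every latency in `a` exceeds every latency in
#' `b` (the `a` population responds consistently later), -1 in the opposite
#' case, and 0 when neither population dominates. Antisymmetric:
#' `dominance_score(a, b) == -dominance_score(b, a)`.
#'
#' @param a,b Non-empty numeric vectors of finite latencies.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' dominance_score(c(1, 2), c(3, 4))
#' @export
dominance_score <- function(a, b) {
  if (!length(a) || !length(b)) abort("Both latency sets must be non-empty.")
  if (anyNA(a) || anyNA(b)) abort("Latencies must be finite (drop undefined estimates first).")
  mean(sign(outer(a, b, "-")))
}

#' Trial-subsampling variability of a latency estimator
#'
#' Repeatedly draws a fraction of the trials without replacement, re-runs
#' the estimator, and reports the standard deviation of the defined
#' estimates. Subsampling without replacement (rather than a conventional
#' bootstrap) avoids superimposed duplicate spikes that would create
#' artifactual peaks in cumulative-deviation statistics. The result is
#' undefined (`NA`) unless the estimator yields a defined latency in at
#' least `validity_threshold` of the subsamples. For bin-based estimators,
#' pass the bin width so half of it is added to the SD, accounting for the
#' temporal quantization that binning imposes.
#'
#' @param spikes Numeric vector of spike times in seconds (or data frame
#'   with `spike_time_s`).
#' @param events Numeric vector of event times (or data frame with
#'   `event_time_s`).
#' @param estimator A function `(spikes, events) -> latency in seconds or
#'   NA`.
#' @param n_iter Number of subsampling iterations (default 250).
#' @param fraction Fraction of trials drawn per iteration (default 0.5).
#' @param validity_threshold Minimum fraction of defined estimates required
#'   (default 0.7).
#' @param bin_width Optional bin width in seconds; when given, half of it is
#'   added to the SD.
#' @param seed Optional integer seed.
#' @return A list with `sd` (seconds, `NA` when below the validity
#'   threshold), `fraction_defined`, `estimates` (per-iteration latencies)
#'   and `n_iter`.
#' @export
subsample_variability <- function(spikes, events, estimator,
                                  n_iter = 250, fraction = 0.5,
                                  validity_threshold = 0.7,
                                  bin_width = NULL, seed = NULL) {
  if (n_iter < 2) abort("`n_iter` must be at least 2.")
  spikes <- as_spike_times(spikes)
  events <- as_event_times(events)
  n_sub <- floor(fraction * length(events))
  if (n_sub < 1) abort("`fraction` leaves no trials to subsample.")
  with_seed(seed, {
    est <- vapply(seq_len(n_iter), function(i) {
      sub <- sort(sample(events, n_sub))
      out <- estimator(spikes, sub)
      if (is.null(out) || !length(out) || !is.finite(out)) NA_real_ else as.double(out)
    }, numeric(1))
    frac_def <- mean(!is.na(est))
    sd_out <- if (frac_def >= validity_threshold && sum(!is.na(est)) >= 2) {
      s <- sd(est[!is.na(est)])
      if (!is.null(bin_width)) s + bin_width / 2 else s
    } else {
      NA_real_
    }
    list(sd = sd_out, fraction_defined = frac_def, estimates = est, n_iter = n_iter)
  })
}

#' Paired-difference bootstrap test
#'
#' Resamples the `N` paired differences `x - y` with replacement, forming a
#' bootstrap distribution of their mean, and reports a percentile confidence
#' interval and an add-one tail-proportion p-value against zero. Two-tailed
#' tests are used for latency comparisons; one-tailed for directional
#' metrics.
#'
#' @param x,y Paired numeric vectors of equal length (`N >= 2`).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param alternative `"two.sided"` (default), `"greater"` (mean difference
#'   above zero) or `"less"`.
#' @param conf_level Confidence level of the percentile interval
#'   (default 0.95).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `estimate` (mean difference), `conf_low`,
#'   `conf_high`, `p_value`, `n`, `n_boot` and `alternative`.
#' @export
bootstrap_paired_diff <- function(x, y, n_boot = 10000,
                                  alternative = c("two.sided", "greater", "less"),
                                  conf_level = 0.95, seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  n <- length(x)
  if (n < 2) abort("Need at least two pairs.")
  d <- x - y
  with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    boots <- colMeans(matrix(d[idx], nrow = n))
    lo_q <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(lo_q, 1 - lo_q)))
    p_le <- (1 + sum(boots <= 0)) / (n_boot + 1)
    p_ge <- (1 + sum(boots >= 0)) / (n_boot + 1)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_le,
      less = p_ge
    )
    tibble(
      estimate = mean(d), conf_low = ci[1], conf_high = ci[2],
      p_value = p, n = n, n_boot = n_boot, alternative = alternative
    )
  })
}

#' Monte Carlo power analysis over empirical latency distributions
#'
#' For each candidate sample size, repeatedly draws samples with replacement
#' from two empirical latency distributions, applies a Wilcoxon test at the
#' given significance level, and estimates power as the proportion of
#' significant simulations. The signed-rank variant treats the two
#' distributions as paired (they must have equal length and a common pair
#' index is resampled); the rank-sum variant draws the groups
#' independently. Also reports the smallest size reaching the `power_goal`.
#'
#' @param dist_a,dist_b Numeric vectors: empirical latency distributions.
#' @param test `"rank_sum"` (independent groups, default) or
#'   `"signed_rank"` (paired).
#' @param sample_sizes Integer vector of per-group sample sizes to evaluate.
#' @param n_sim Simulations per sample size (default 1000).
#' @param alpha Significance level of each test (default 0.05).
#' @param power_goal Target power defining the minimal sufficient sample
#'   size (default 0.8).
#' @param seed Optional integer seed.
#' @return An object of class `power_curve`: a list with `curve` (tibble of
#'   `sample_size`, `power`), `n_sufficient` (smallest size with power at or
#'   above `power_goal`, `NA` if never reached), plus the settings.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
power_analysis <- function(dist_a, dist_b,
                           test = c("rank_sum", "signed_rank"),
                           sample_sizes, n_sim = 1000, alpha = 0.05,
                           power_goal = 0.8, seed = NULL) {
  test <- match.arg(test)
  if (!length(dist_a) || !length(dist_b)) abort("Both distributions must be non-empty.")
  if (test == "signed_rank" && length(dist_a) != length(dist_b)) {
    abort("`signed_rank` requires paired distributions of equal length.")
  }
  sample_sizes <- as.integer(sample_sizes)
  with_seed(seed, {
    power <- vapply(sample_sizes, function(n) {
      sig <- vapply(seq_len(n_sim), function(s) {
        if (test == "signed_rank") {
          idx <- sample.int(length(dist_a), n, replace = TRUE)
          p <- suppressWarnings(
            wilcox.test(dist_a[idx], dist_b[idx], paired = TRUE, exact = FALSE)$p.value
          )
        } else {
          xa <- sample(dist_a, n, replace = TRUE)
          xb <- sample(dist_b, n, replace = TRUE)
          p <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
        }
        is.finite(p) && p < alpha
      }, logical(1))
      mean(sig)
    }, numeric(1))
    reached <- sample_sizes[power >= power_goal]
    structure(
      list(
        curve = tibble(sample_size = sample_sizes, power = power),
        n_sufficient = if (length(reached)) min(reached) else NA_integer_,
        test = test, n_sim = n_sim, alpha = alpha, power_goal = power_goal
      ),
      class = "power_curve"
    )
  })
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Monte Carlo power curve (%s test, alpha = %g, %d sims/size)\n",
              x$test, x$alpha, x$n_sim))
  print(x$curve, n = nrow(x$curve))
  if (is.na(x$n_sufficient)) {
    cat(sprintf("  power %g not reached at the tested sizes\n", x$power_goal))
  } else {
    cat(sprintf("  smallest size with power >= %g: %d\n", x$power_goal, x$n_sufficient))
  }
  invisible(x)
}
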