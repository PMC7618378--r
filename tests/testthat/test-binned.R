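test_that("PETH construction normalizes counts to rates and conserves spikes", {
  ev <- c(10, 20, 30)
  # No spikes: all-zero rates.
  p0 <- build_peth(numeric(0), ev, -0.1, 0.5, 0.01)
  expect_true(all(p0$rates == 0))
  expect_length(p0$rates, 60)

  # One spike per event in the same 10 ms bin: rate = 1 / (0.01 s) = 100 sp/s.
  sp <- ev + 0.055
  p1 <- build_peth(sp, ev, -0.1, 0.5, 0.01)
  expect_equal(max(p1$rates), 100)
  expect_equal(sum(p1$rates > 0), 1)

  # Total spike count conserved: sum(rates) * bin_width * n_events.
  set.seed(1)
  sp2 <- sort(runif(400, 9, 31))
  p2 <- build_peth(sp2, ev, -0.1, 0.5, 0.01)
  expect_equal(sum(p2$rates) * 0.01 * 3, length(align_spikes(sp2, ev, -0.1, 0.5)))

  # Partial terminal bin is dropped, not rescaled.
  p3 <- build_peth(numeric(0), ev, -0.1, 0.45, 0.1)
  expect_length(p3$rates, 5)
  expect_error(build_peth(sp2, ev, -0.1, 0.5, 0.7), "smaller than the window")
})

test_that("half-max latency matches the hand-worked example", {
  # Baseline bins all at 2 sp/s; post bins [2, 10, 6, ...]; 10 ms bins from onset.
  peth <- fake_peth(c(2, 2, 2, 2, 2, 2, 10, 6, 4, 2), bin_width = 0.01, t0 = -0.05)
  # lambda_B = 2, peak deviation 8, threshold 4 -> second post bin, center 15 ms.
  expect_equal(half_max_latency(peth), 0.015)

  # Flat PETH: peak deviation 0, nothing strictly exceeds it -> undefined.
  expect_true(is.na(half_max_latency(fake_peth(rep(3, 10), 0.01, -0.05))))

  # Suppressed responses are detected through the absolute deviation.
  supp <- fake_peth(c(8, 8, 8, 8, 8, 1, 2, 8, 8, 8), bin_width = 0.01, t0 = -0.05)
  expect_equal(half_max_latency(supp), 0.005)
})

test_that("SD-threshold latency matches the hand-worked example", {
  # Baseline [1, 3, 1, 3]: mean 2, sample sd = 2/sqrt(3) ~ 1.1547.
  peth <- fake_peth(c(1, 3, 1, 3, 2, 6, 9), bin_width = 0.01, t0 = -0.04)
  # Threshold 2.58 * 1.1547 ~ 2.979; first post deviation > threshold is |6-2| = 4.
  expect_equal(sd_threshold_latency(peth), 0.015)

  # Post bins identical to the baseline mean: undefined.
  flat <- fake_peth(c(1, 3, 1, 3, 2, 2, 2), bin_width = 0.01, t0 = -0.04)
  expect_true(is.na(sd_threshold_latency(flat)))

  # Degenerate zero-SD baseline: undefined with a flag, not a spurious hit.
  degen <- fake_peth(c(2, 2, 2, 2, 9, 9), bin_width = 0.01, t0 = -0.04)
  out <- sd_threshold_latency(degen)
  expect_true(is.na(out))
  expect_true(isTRUE(attr(out, "degenerate_baseline")))
})

test_that("a smaller k never yields a later SD-threshold latency", {
  set.seed(5)
  for (rep in 1:10) {
    rates <- c(abs(rnorm(5, 2)), abs(rnorm(10, 4, 3)))
    peth <- fake_peth(rates, 0.01, -0.05)
    l1 <- sd_threshold_latency(peth, k = 1)
    l2 <- sd_threshold_latency(peth, k = 2.58)
    if (is.finite(l2)) expect_lte(l1, l2)
  }
})

test_that("bin-based latencies are quantized to bin centers", {
  sim <- simulate_step_response(n_events = 80, baseline_rate = 2,
                                response_rate = 30, onset = 0.1, seed = 4)
  peth <- build_peth(sim$spikes, sim$events, -0.2, 0.6, 0.01)
  for (lat in c(half_max_latency(peth), sd_threshold_latency(peth))) {
    if (is.finite(lat)) expect_true(any(abs(peth$centers - lat) < 1e-12))
  }
})

test_that("difference PETH subtracts binwise and requires matching edges", {
  ev_a <- c(5, 15); ev_b <- c(25, 35)
  set.seed(2)
  sp <- sort(runif(300, 0, 40))
  pa <- build_peth(sp, ev_a, -0.1, 0.5, 0.02)
  pb <- build_peth(sp, ev_b, -0.1, 0.5, 0.02)
  d <- difference_peth(pa, pb)
  expect_equal(d$rates, pa$rates - pb$rates)
  expect_equal(difference_peth(pb, pa)$rates, -d$rates)
  expect_true(all(difference_peth(pa, pa)$rates == 0))
  pc <- build_peth(sp, ev_b, -0.1, 0.5, 0.01)
  expect_error(difference_peth(pa, pc), "identical bin edges")
})

test_that("difference-PETH half-max finds a divergence near the true time", {
  # Clean divergence without a shared transient (which at 5 ms bins injects
  # baseline-difference noise that the half-max rule is known to chase).
  lats <- vapply(1:5, function(s) {
    sim <- simulate_two_condition(baseline_rate = 2, transient_rate = 2,
                                  sustained_a = 30, sustained_b = 2,
                                  seed = 900 + s)
    pa <- build_peth(sim$spikes, sim$events_a, -0.1, 1, 0.005)
    pb <- build_peth(sim$spikes, sim$events_b, -0.1, 1, 0.005)
    half_max_latency(difference_peth(pa, pb))
  }, numeric(1))
  expect_true(all(is.finite(lats)))
  expect_lt(abs(median(lats) - 0.15), 0.05)
})

test_that("the bin-width grid is 11 log-spaced values from 0.5 to 50 ms", {
  g <- bin_width_grid()
  expect_length(g, 11)
  expect_equal(g[1], 5e-4)
  expect_equal(g[11], 5e-2)
  expect_true(all(diff(g) > 0))
  ratios <- g[-1] / g[-11]
  expect_equal(ratios, rep(ratios[1], 10))
})
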