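test_that("per-event cumulative counts normalize by the event count", {
  expect_equal(per_event_cumulative(1:8 / 10, 4), (1:8) / 4)
  expect_length(per_event_cumulative(numeric(0), 5), 0)
  v <- sort(runif(12))
  expect_equal(per_event_cumulative(v, 6), per_event_cumulative(v, 3) / 2)
})

test_that("merged grid is the deduplicated sorted union", {
  expect_equal(merged_grid(0.1, 0.2), c(0.1, 0.2))
  v <- c(0.1, 0.5, 0.9)
  expect_equal(merged_grid(v, v), v)
  a <- sort(runif(20)); b <- sort(runif(15))
  expect_lte(length(merged_grid(a, b)), 35)
  expect_error(merged_grid(numeric(0), numeric(0)), "empty")
})

test_that("cumulative interpolation hits knots, midpoints and extrapolation rules", {
  v <- c(0.2, 0.4, 0.8)
  cum <- c(1, 2, 3)
  expect_equal(interpolate_cumulative(v, cum, v), cum)
  expect_equal(interpolate_cumulative(v, cum, 0.3), 1.5)
  expect_equal(interpolate_cumulative(v, cum, c(0.0, 0.1)), c(0, 0)) # before all
  expect_equal(interpolate_cumulative(v, cum, 0.9), 3)               # beyond all
  expect_equal(interpolate_cumulative(numeric(0), numeric(0), c(0.1, 0.2)), c(0, 0))
})

test_that("detrended difference removes constant rate offsets exactly", {
  # Identical conditions: difference and detrended difference vanish.
  v <- sort(runif(30))
  tr <- difference_trace(v, v, 10, 10)
  expect_equal(tr$difference, rep(0, length(tr$times)))
  expect_equal(tr$deviation, rep(0, length(tr$times)))

  # Same spike times with different trial counts on an equally spaced grid:
  # the difference is affine in time, so detrending leaves exactly zero.
  v_eq <- seq(0.1, 1, by = 0.1)
  tr2 <- difference_trace(v_eq, v_eq, 5, 10)
  expect_true(all(abs(tr2$deviation) < 1e-12))
  expect_gt(max(abs(tr2$difference)), 0)
})

test_that("detrended difference endpoints are exactly zero and swapping negates", {
  set.seed(6)
  for (rep in 1:10) {
    va <- sort(runif(sample(5:40, 1)))
    vb <- sort(runif(sample(5:40, 1)))
    tr <- difference_trace(va, vb, 7, 9)
    n <- length(tr$times)
    expect_identical(tr$deviation[1], 0)
    expect_identical(tr$deviation[n], 0)
    sw <- difference_trace(vb, va, 9, 7)
    expect_equal(sw$difference, -tr$difference)
    expect_equal(sw$deviation, -tr$deviation)
  }
  expect_error(difference_trace(0.5, numeric(0), 3, 3), "two distinct")
})

test_that("trial-swap null is reproducible, non-negative and counter-seeded", {
  sim <- simulate_two_condition(n_events_a = 20, n_events_b = 20, seed = 2)
  sets <- latenzy:::align_spikes_by_event(sim$spikes, sim$events, -0.1, 1)
  n1 <- shuffle_null(sets, 20, 20, n_resamples = 30, seed = 77)
  n2 <- shuffle_null(sets, 20, 20, n_resamples = 30, seed = 77)
  n3 <- shuffle_null(sets, 20, 20, n_resamples = 50, seed = 77)
  expect_length(n1, 30)
  expect_true(all(n1 >= 0))
  expect_identical(n1, n2)
  expect_identical(n3[1:30], n1)
})

test_that("condition labels can be swapped without changing the estimate", {
  sim <- simulate_two_condition(n_events_a = 80, n_events_b = 80, seed = 12)
  f_ab <- latenzy2(sim$spikes, sim$events_a, sim$events_b, t0 = -0.1, t1 = 1,
                   n_resamples = 100, seed = 55)
  f_ba <- latenzy2(sim$spikes, sim$events_b, sim$events_a, t0 = -0.1, t1 = 1,
                   n_resamples = 100, seed = 55)
  expect_true(f_ab$defined)
  expect_equal(f_ab$latency, f_ba$latency)
})

test_that("two-condition data frames with condition labels are accepted", {
  sim <- simulate_two_condition(n_events_a = 50, n_events_b = 50, seed = 14)
  ev <- tibble::tibble(event_time_s = sim$events, condition = sim$condition)
  f_df <- latenzy2(sim$spikes, ev, t0 = -0.1, t1 = 1,
                   cond_a = "a", cond_b = "b", n_resamples = 100, seed = 31)
  f_vec <- latenzy2(sim$spikes, sim$events_a, sim$events_b, t0 = -0.1, t1 = 1,
                    n_resamples = 100, seed = 31)
  expect_equal(f_df$latency, f_vec$latency)
})

test_that("a sustained-rate divergence is recovered near its true time", {
  sim <- simulate_two_condition(seed = 3)
  fit <- latenzy2(sim$spikes, sim$events_a, sim$events_b, t0 = -0.1, t1 = 1, seed = 3)
  expect_true(fit$defined)
  expect_lt(abs(fit$latency - sim$true_divergence), 0.03)
  it <- tidy(fit)
  expect_true(all(diff(it$t1) < 0))
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("both conditions empty give an undefined result", {
  fit <- latenzy2(numeric(0), c(1, 2), c(3, 4), t0 = -0.1, t1 = 0.5, seed = 1)
  expect_false(fit$defined)
  expect_true(is.na(fit$latency))
})
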