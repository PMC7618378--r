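test_that("thinning sampler matches homogeneous-Poisson statistics", {
  expect_length(simulate_poisson_spikes(0, 10, seed = 1), 0)

  # Expected count lambda * D = 1e4; a single draw stays within 4 SD.
  sp <- simulate_poisson_spikes(100, 100, seed = 2)
  expect_lt(abs(length(sp) - 1e4), 4 * sqrt(1e4))
  expect_false(is.unsorted(sp))
  expect_true(all(sp >= 0 & sp < 100))

  # Inter-spike intervals of a constant-rate train are exponential.
  ks <- suppressWarnings(ks.test(diff(sp), "pexp", rate = 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("thinning validates the rate bound", {
  expect_error(simulate_poisson_spikes(function(t) -1 + 0 * t, 10, peak_rate = 5, seed = 1),
               "negative")
  expect_error(simulate_poisson_spikes(function(t) 10 + 0 * t, 10, peak_rate = 5, seed = 1),
               "exceeds")
  expect_error(simulate_poisson_spikes(function(t) t, 10), "peak_rate")
})

test_that("simulations are bit-exact from the seed", {
  s1 <- simulate_step_response(n_events = 30, seed = 5)
  s2 <- simulate_step_response(n_events = 30, seed = 5)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_step_response(n_events = 30, seed = 6)
  expect_false(identical(s1$spikes, s3$spikes))

  t1 <- simulate_two_condition(n_events_a = 20, n_events_b = 20, seed = 5)
  t2 <- simulate_two_condition(n_events_a = 20, n_events_b = 20, seed = 5)
  expect_identical(t1$spikes, t2$spikes)
  expect_identical(t1$condition, t2$condition)
})

test_that("step scenario places extra spikes only inside the response window", {
  sim <- simulate_step_response(n_events = 200, baseline_rate = 5,
                                response_rate = 40, onset = 0.1,
                                response_duration = 0.3, seed = 7)
  v <- align_spikes(sim$spikes, sim$events, -0.5, 0.8)
  rate_resp <- sum(v >= 0.1 & v < 0.4) / (0.3 * 200)
  rate_base <- sum(v < 0.1) / (0.6 * 200)
  expect_gt(rate_resp, 30)
  expect_lt(rate_base, 8)
  expect_equal(sim$true_onset, 0.1)

  # Zero response probability degenerates to homogeneous firing.
  null <- simulate_step_response(n_events = 200, baseline_rate = 5,
                                 response_rate = 40, onset = 0.1,
                                 response_probability = 0, seed = 8)
  vb <- align_spikes(null$spikes, null$events, -0.5, 0.8)
  rate_all <- length(vb) / (1.3 * 200)
  expect_lt(abs(rate_all - 5), 0.5)
})

test_that("partial response consistency scales the evoked rate", {
  half <- simulate_step_response(n_events = 400, baseline_rate = 0,
                                 response_rate = 20, onset = 0,
                                 response_duration = 0.5,
                                 response_probability = 0.5, seed = 9)
  # Expected spikes: 400 * 0.5 * 20 * 0.5 = 2000; binomial/Poisson noise ~ 70.
  expect_lt(abs(length(half$spikes) - 2000), 300)
})

test_that("two-condition rates are identical before divergence and differ after", {
  sim <- simulate_two_condition(n_events_a = 200, n_events_b = 200, seed = 10)
  va <- align_spikes(sim$spikes, sim$events_a, -0.1, 1)
  vb <- align_spikes(sim$spikes, sim$events_b, -0.1, 1)
  pre_a <- sum(va < 0.15) / 200; pre_b <- sum(vb < 0.15) / 200
  post_a <- sum(va >= 0.15) / 200; post_b <- sum(vb >= 0.15) / 200
  # Shared segment: ~5.75 expected spikes/trial each; Poisson SE ~ 0.17.
  expect_lt(abs(pre_a - pre_b), 0.7)
  # Diverged segment: 20 vs 10 sp/s over 0.85 s.
  expect_gt(post_a - post_b, 5)
  expect_equal(sim$true_divergence, 0.15)
  expect_setequal(c(sim$events_a, sim$events_b), sim$events)
})

test_that("simulated sessions round-trip through the CSV writers", {
  sim <- simulate_two_condition(n_events_a = 15, n_events_b = 15, seed = 11)
  dir <- tmp_dir()
  write_spike_times(sim$spikes, file.path(dir, "spikes.csv"))
  write_event_times(sim$events, file.path(dir, "events.csv"),
                    condition = sim$condition)
  sp <- read_spike_times(file.path(dir, "spikes.csv"))
  ev <- read_event_times(file.path(dir, "events.csv"))
  expect_equal(sp, sim$spikes, tolerance = 1e-6)
  expect_equal(ev$event_time_s, sim$events, tolerance = 1e-6)
  expect_equal(ev$condition, sim$condition)
})
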