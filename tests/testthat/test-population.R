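test_that("monotonicity score is the mean sign of successive differences", {
  expect_equal(monotonicity_score(c(5, 4, 3, 2, 1)), -1)
  expect_equal(monotonicity_score(c(1, 2, 1, 2, 1)), 0)
  expect_equal(monotonicity_score(c(1, 1, 2)), 0.5) # tie contributes 0
  expect_error(monotonicity_score(3), "at least two")
  set.seed(1)
  for (rep in 1:10) {
    s <- monotonicity_score(rnorm(sample(2:20, 1)))
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("dominance score counts pairwise comparisons and is antisymmetric", {
  expect_equal(dominance_score(c(1, 2), c(3, 4)), -1)
  expect_equal(dominance_score(c(1, 3), 2), 0)
  expect_equal(dominance_score(c(2, 2), c(2, 2)), 0)
  set.seed(2)
  for (rep in 1:10) {
    a <- rnorm(sample(1:15, 1)); b <- rnorm(sample(1:15, 1))
    d <- dominance_score(a, b)
    expect_equal(d, -dominance_score(b, a))
    expect_gte(d, -1); expect_lte(d, 1)
    # Brute-force oracle over all pairs.
    cnt <- outer(a, b, "-")
    expect_equal(d, (sum(cnt > 0) - sum(cnt < 0)) / (length(a) * length(b)))
  }
})

test_that("subsampling variability handles constant, sparse and binned estimators", {
  sim <- null_session(n_events = 40, seed = 3)
  const <- function(spikes, events) 0.123
  out <- subsample_variability(sim$spikes, sim$events, const, n_iter = 20, seed = 1)
  expect_equal(out$sd, 0)
  expect_equal(out$fraction_defined, 1)

  # Defined in only 60% of subsamples: below the 70% validity threshold.
  counter <- new.env(); counter$i <- 0
  sparse <- function(spikes, events) {
    counter$i <- counter$i + 1
    if (counter$i %% 5 %in% c(1, 2)) NA_real_ else 0.1
  }
  out2 <- subsample_variability(sim$spikes, sim$events, sparse, n_iter = 20, seed = 1)
  expect_equal(out2$fraction_defined, 0.6)
  expect_true(is.na(out2$sd))

  # Bin-based estimators: half the bin width is added to the SD.
  out3 <- subsample_variability(sim$spikes, sim$events, const, n_iter = 20,
                                bin_width = 0.01, seed = 1)
  expect_equal(out3$sd, 0.005)
  expect_error(subsample_variability(sim$spikes, sim$events, const, n_iter = 1),
               "at least 2")
})

test_that("paired bootstrap flags clear effects and stays silent on null data", {
  z <- bootstrap_paired_diff(rep(1, 10), rep(1, 10), n_boot = 200, seed = 1)
  expect_equal(z$estimate, 0)
  expect_equal(c(z$conf_low, z$conf_high), c(0, 0))
  expect_gte(z$p_value, 0.99)

  one <- bootstrap_paired_diff(rep(2, 10), rep(1, 10), n_boot = 200, seed = 1)
  expect_equal(one$estimate, 1)
  expect_gt(one$conf_low, 0)
  expect_lt(one$p_value, 0.05)
  expect_error(bootstrap_paired_diff(1:3, 1:4), "paired")
})

test_that("bootstrap percentile CI agrees with the t-interval on normal data", {
  set.seed(5)
  d <- rnorm(100, 0.5, 1)
  boot <- bootstrap_paired_diff(d, rep(0, 100), n_boot = 5000, seed = 6)
  # Closed-form oracle: the t-interval for the same differences.
  tt <- stats::t.test(d)
  t_half <- diff(tt$conf.int) / 2
  boot_half <- (boot$conf_high - boot$conf_low) / 2
  expect_lt(abs(boot_half - t_half), 0.1 * t_half)
  expect_lt(abs(mean(c(boot$conf_low, boot$conf_high)) - mean(d)), 0.1 * t_half)
})

test_that("power analysis is calibrated under the null and saturates when separated", {
  set.seed(7)
  a <- rnorm(300)
  pw_null <- power_analysis(a, a, test = "rank_sum", sample_sizes = 20,
                            n_sim = 400, seed = 8)
  expect_gte(pw_null$curve$power, 0.01)
  expect_lte(pw_null$curve$power, 0.10)

  pw_sep <- power_analysis(rnorm(200), rnorm(200, 10), sample_sizes = c(5, 10),
                           n_sim = 200, seed = 9)
  expect_gte(pw_sep$curve$power[2], 0.95)
  expect_equal(pw_sep$n_sufficient, 5)
})

test_that("rank-sum power at n = 23 for a unit shift of a standard normal is ~0.90", {
  # Reference value 0.893 from a large independent Monte Carlo evaluation of
  # the same test at this effect size.
  set.seed(10)
  a <- rnorm(4000); b <- rnorm(4000, 1)
  pw <- power_analysis(a, b, test = "rank_sum", sample_sizes = 23,
                       n_sim = 1500, seed = 11)
  expect_lt(abs(pw$curve$power - 0.893), 0.03)
})

test_that("power is non-decreasing in sample size for separated distributions", {
  set.seed(12)
  a <- rnorm(500); b <- rnorm(500, 0.8)
  pw <- power_analysis(a, b, test = "rank_sum", sample_sizes = c(5, 15, 40),
                       n_sim = 400, seed = 13)
  slack <- 2 / sqrt(400)
  expect_true(all(diff(pw$curve$power) > -slack))
  expect_s3_class(autoplot(pw), "ggplot")
  expect_equal(nrow(tidy(pw)), 3)
})

test_that("signed-rank power analysis resamples pairs jointly", {
  set.seed(14)
  a <- rnorm(200); b <- a + rnorm(200, 0.8, 0.2) # strongly paired shift
  pw <- power_analysis(a, b, test = "signed_rank", sample_sizes = c(8, 16),
                       n_sim = 200, seed = 15)
  expect_true(all(diff(pw$curve$power) > -0.15))
  expect_gte(pw$curve$power[2], 0.9)
  expect_error(power_analysis(1:3, 1:4, test = "signed_rank", sample_sizes = 5),
               "paired")
})
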