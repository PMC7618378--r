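---
title: "Binning-free latency estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning-free latency estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latenzy)
```

## The problem

A response latency is the time between an event — a stimulus onset, a cue, a
movement — and the first detectable change in a neuron's spiking. Most
latency estimators first bin spikes into a peri-event time histogram (PETH)
and then apply a threshold rule, which makes the estimate depend on two
arbitrary choices: the bin width and the threshold. This package implements
a binning-free alternative that works directly on spike times, in two
flavours: a one-sample estimator of response onset (`latenzy()`), and a
two-sample estimator of the earliest time at which spiking diverges between
two experimental conditions (`latenzy2()`). It also implements the two
standard bin-based rules (half-max and SD-threshold) as comparators, the
population-level benchmark statistics used to evaluate latency methods, and
seeded spike-train simulators with known ground truth.

## The one-sample model

Given spike times $x_1, \dots, x_n$ and event times $w_1, \dots, w_q$, an
analysis window $[t_0, t_1]$ with $T = t_1 - t_0$ is placed around each
event. Spike membership is half-open on the left: spike $x$ belongs to
event $w$ iff $w + t_0 < x \le w + t_1$. Each refinement iteration performs
four steps.

**Stitching.** Spikes falling between consecutive event windows
($w_k + t_1 < x \le w_{k+1} + t_0$) are removed and all later spike and
event times are shifted back by the cumulative excluded duration
$e_j = \max(w_{j+1} - w_j - T,\, 0)$. After stitching, no inter-event gap
exceeds $T$, and event-relative spike times are untouched. Stitching is
applied once per iteration, on the real data, *before* the null resampling:
the jittered and observed statistics then see identical temporal segments.

**Cumulative deviation.** Event-relative spike times are pooled across
events and sorted; two artificial boundary spikes at $t_0$ and $t_1$ ensure
full-epoch coverage. With $g_i = i/n$ the fractional position of the
$i$-th pooled spike and $b_i = (v_i - t_0)/T$ the linear baseline expected
under temporally unmodulated firing, the deviation is
$\delta_i = g_i - b_i$. The test statistic is the signed extremal value
$\zeta$ of $\boldsymbol{\delta}$ (the minimum when
$|\min| \ge |\max|$, ties to the minimum) and its associated time
$\tau_\zeta$; arg-extremum ties resolve to the earliest index.

**Jitter null and Gumbel p-value.** The null distribution is built by
shifting every event time by an independent Uniform$(-T, T)$ draw and
recomputing the mean-normalized absolute extremal deviation
$\tilde\zeta = |\zeta - \bar\delta|$, $M$ times. A Gumbel extreme-value law
is fitted to the $M$ null values by the method of moments
($\beta = \sqrt{6\,\mathrm{var}}/\pi$,
$\mu = \mathrm{mean} - \gamma\beta$ with $\gamma$ the Euler–Mascheroni
constant) and the p-value is the upper-tail probability
$p = 1 - \exp[-\exp(-(\tilde\zeta_r - \mu)/\beta)]$. An empirical
quantile-position route (add-one estimator,
$p = (1 + \#\{\text{null} \ge \tilde\zeta_r\})/(M+1)$) is available via
`p_method = "empirical"`; the Gumbel route is the default because it
resolves p-values below $1/(M+1)$ at moderate $M$.

**Refinement.** While $p < \alpha$, the window shrinks to
$[t_0, \tau_\zeta]$ and the procedure repeats; the upper bound is inclusive
under the half-open convention, so the spike at $\tau_\zeta$ stays in the
window. When an iteration is non-significant, the estimate is the extremal
time of the *previous* (last significant) iteration. If the very first
iteration is non-significant the latency is undefined — reported as
`defined = FALSE`, never as an arbitrary number. The rationale: with many
trials the cumulative distribution of pooled spike times is linear during
purely spontaneous activity, so the extremal deviation can only occur at or
after the onset of time-locked activity; trimming from above walks the
extremum back to the transition.

## The two-sample model

For conditions $a$ and $b$ sharing the same window, pooled event-relative
spike times are converted to *per-event* cumulative counts
$c_i = i/q$ (spikes per event), which makes unequal trial counts directly
comparable. Both cumulative vectors are linearly interpolated onto the
merged grid of all spike times (constant extrapolation: 0 before the first
sample, the final count after the last), and their difference $\Delta$ is
detrended by subtracting the straight line through its endpoints — a
constant rate offset between conditions produces exactly such a line, so
detrending isolates transient divergence. The extremal of the detrended
difference and its time are tested against a trial-swap null: the per-event
spike sets of both conditions are pooled, $q^a$ sets are drawn without
replacement as pseudo-condition $a$, and the complement forms
pseudo-condition $b$. Iterative refinement then proceeds exactly as above.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `alpha` | 0.05 | probability | refinement-stopping significance level |
| `n_resamples` (`latenzy`) | 100 | count | event-jitter resamples per iteration |
| `n_resamples` (`latenzy2`) | 250 | count | trial-swap resamples per iteration |
| `p_method` | `"gumbel"` | — | p-value route |
| `min_spikes` | 3 | count | minimum pooled spikes to attempt an iteration |
| `restrict_positive` | `FALSE` | — | reject non-positive candidate latencies |
| `k` (SD-threshold) | 2.58 | SDs | two-tailed normal critical value at 0.01 |
| bin-width grid | 0.5–50 ms | s | 11 log-spaced PETH widths |
| `min_rate_filter` | 0.1 | spikes/s | batch-level unit exclusion |

`restrict_positive` exists for benchmarking against the bin-based rules,
which are restricted to post-onset responses by construction. It is
implemented by treating a non-positive candidate extremal time as a
stopping event (returning the last positive significant latency) rather
than by truncating the window at zero, which would alter the null
construction relative to the unrestricted case.

## Numerical and design choices

* **Window membership** is uniformly half-open, $(t_0, t_1]$. The boundary
  convention matters only for spikes exactly on an edge; a single
  consistent rule keeps stitching, alignment and binning mutually
  consistent.
* **Tie rules** are deterministic: $|\min| \ge |\max|$ selects the minimum;
  equal extremal values select the earliest time. An all-zero deviation
  (degenerate inputs) yields statistic 0, which is never significant.
* **Duplicate spike times** (multi-unit data) are retained everywhere
  except in the merged two-sample grid, where duplicated *grid points* are
  collapsed — repeated abscissae add no information and break
  interpolation monotonicity. Cumulative values at a duplicated sample time
  take the upper count.
* **Detrending** uses the convex-weight form
  $(1-\omega)\Delta_1 + \omega\Delta_N$, which guarantees the detrended
  difference is *exactly* zero at both endpoints in floating point.
* **Boundary spikes** are used only by the one-sample estimator; the
  two-sample trace covers the window through its extrapolation rules
  instead, so no artificial mass enters the difference statistic.
* **Gumbel tail** is computed as `-expm1(-exp(·))` to stay accurate for
  small p; a zero-variance null (all resamples identical) falls back to
  the empirical route with a `degenerate_null` flag.
* **Trial-swap split**: pseudo-condition $b$ receives the complement of the
  $a$ draw. A permutation split preserves exchangeability and total spike
  mass exactly, unlike two independent draws.
* **Jittered events** are re-sorted but not clipped to the recording;
  stitching has already restricted the data to the event neighbourhood, and
  clipping would bias edge events' jitter distribution.
* **Seeding**: every stochastic function takes an optional `seed`;
  resample $m$ of a loop uses a counter-derived stream (`seed + m`), so
  increasing the resample count extends rather than reshuffles the null,
  and per-iteration streams are offset far apart. Global RNG state is
  restored on exit.
* **Termination** is guaranteed: each significant iteration strictly
  decreases $t_1$ to a spike time inside the previous window; an extremal
  time equal to the current bound, a non-positive candidate under
  `restrict_positive`, or fewer than `min_spikes` pooled spikes all stop
  the loop and return the result so far. The minimum spike count is an
  implementation choice (deviations from one or two spikes are vacuous).
* **Wilcoxon tests** inside the power analysis use the normal approximation
  with tie correction: resampling from empirical distributions with
  replacement produces ties with near-certainty, which rules out the exact
  distribution anyway.
* **Bootstrap p-values** use the add-one tail proportion of resampled mean
  differences beyond zero (doubled and capped for two-sided tests), and no
  multiple-comparison correction is applied by default.

## What the simulators emulate — and what they do not

`simulate_step_response()` generates regularly spaced events and
inhomogeneous-Poisson spiking that steps from a baseline to a response rate
at a known onset, for a known duration, with a per-event response
probability (response consistency). `simulate_two_condition()` interleaves
two randomly ordered event sets whose profiles share a baseline, an onset
transient and a sustained level, diverging only in sustained rate after a
known time. Both use Lewis–Shedler thinning, which is exact for bounded
rate functions, and are bit-reproducible from their seed.

Default two-condition settings encode a shared transient of 50 spikes/s
over the first 100 ms, sustained rates of 20 versus 10 spikes/s from
+150 ms to +1 s, a 5 spikes/s baseline, and 150 trials per condition at
1.5 s spacing; the step scenario defaults to a 5 → 40 spikes/s step at
+100 ms lasting 500 ms. These are typical cortical orders of magnitude:
strong sensory-driven responses, trial counts of modern population
recordings.

The simulators deliberately omit several features of real spike trains:
refractoriness and bursting (spiking is conditionally Poisson),
trial-to-trial latency jitter and amplitude variability beyond the binary
response-consistency flag, slow non-stationarity of the baseline, and
correlated multi-unit contamination. Passing calibration and recovery
tests on these simulations therefore demonstrates correctness of the
statistics under the stated model, not robustness to every pathology of
recorded data. On real recordings the batch interface additionally
excludes units below 0.1 spikes/s; no non-stationarity screen is applied —
users who need one must pre-filter their units.

## Validation problem sizes

The package's test suite validates, at fixed seeds: type-I calibration of
both estimators over 500 simulated null sessions each (homogeneous
Poisson at 10 spikes/s with 100 events for the one-sample test; identical
conditions with 50 + 50 trials for the two-sample test), checked against
the 99% binomial interval around $\alpha = 0.05$; onset recovery over 100
step-scenario sessions (200 events) with a sub-10-ms median error bound;
divergence recovery over 100 two-condition sessions (150 + 150 trials)
with a sub-20-ms bound; and qualitative parameter sweeps (detection rate
versus response amplitude and trial count, latency error versus spike
count) at 30–40 sessions per grid point. The sweep sizes keep the full
suite within a few minutes on a single core while leaving Monte-Carlo
noise well below the asserted trend margins.

## Known limitations

* One latency per unit: spikes are pooled over trials, so trial-to-trial
  latency variability is invisible by design.
* Weak or inconsistent responses legitimately return `defined = FALSE`;
  population analyses must handle undefined estimates (the subsampling
  variability routine, for example, requires 70% defined subsamples).
* The two-sample estimator is strictly pairwise; multi-condition designs
  need a different framework.
* The Gumbel approximation is asymptotic in $M$; at the default resample
  counts its mid-range agreement with the empirical route is part of the
  test suite, but extreme tail p-values should be read as approximate.

## A worked example

```{r example, eval = FALSE}
library(latenzy)

sim <- simulate_step_response(
  n_events = 200, baseline_rate = 5, response_rate = 40,
  onset = 0.1, seed = 42
)
fit <- latenzy(sim$spikes, sim$events, t0 = -0.2, t1 = 1, seed = 42)
fit
tidy(fit)    # one row per refinement iteration
glance(fit)  # one-row summary
autoplot(fit)

sim2 <- simulate_two_condition(seed = 3)
fit2 <- latenzy2(sim2$spikes, sim2$events_a, sim2$events_b,
                 t0 = -0.1, t1 = 1, seed = 3)
fit2
```
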