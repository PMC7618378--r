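# Shared fixtures, built in code at test time.

# A small homogeneous-Poisson session: no time-locked structure.
null_session <- function(n_events = 100, rate = 10, seed = 1,
                         inter_event_interval = 1.5) {
  simulate_step_response(
    n_events = n_events, baseline_rate = rate, response_rate = rate,
    onset = 0.1, inter_event_interval = inter_event_interval, seed = seed
  )
}

tmp_dir <- function() {
  d <- tempfile("latenzy-test-")
  dir.create(d)
  d
}

# Hand-buildable PETH object for exercising the latency rules directly.
fake_peth <- function(rates, bin_width, t0) {
  n <- length(rates)
  edges <- t0 + bin_width * (0:n)
  structure(
    list(bin_edges = edges, centers = edges[-1] - bin_width / 2,
         rates = rates, bin_width = bin_width, n_events = 1L),
    class = "peth"
  )
}
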