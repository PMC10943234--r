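# Fixtures are built in code at test time; no binary data ships with the
# package.

# A standard seeded trimodal session: schedule + directly simulated trace.
trimodal_fixture <- function(seed = 42, total_frames = 3001) {
  cfg <- scene_config(seed = seed)
  schedule <- sample_schedule(cfg, total_frames = total_frames)
  list(cfg = cfg, schedule = schedule,
       trace = simulate_trace(schedule, seed = seed + 1))
}

# A cheap mixture fit for unit tests (full 300-restart fits live in the
# acceptance suite).
quick_fit <- function(trace, seed = 7, n_restarts = 25) {
  fit_mixture(trace, mixture_config(n_restarts = n_restarts, seed = seed))
}

# Well-separated reference model used where a fit is not itself under test.
reference_model <- function() {
  override_components(NULL, means = c(0.955, 0.975, 0.995),
                      sds = c(0.004, 0.004, 0.002),
                      weights = c(0.3, 0.3, 0.4),
                      trace = similarity_trace(c(0.95, 0.97, 0.99)))
}

# Random grayscale frame on [0, 255].
random_frame <- function(nr = 16, nc = 16) {
  matrix(runif(nr * nc, 0, 255), nr, nc)
}
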