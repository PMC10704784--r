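# Shared helpers: small deterministic objects used across test files.

quick_rate <- function(values, fs = 50, t0 = 0) {
  uniform_signal(values, fs = fs, t0 = t0, kind = "rate")
}

# sinusoidal rate signal with given period
sine_rate <- function(period, duration, fs = 2, base = 10, depth = 0.8,
                      noise_sd = 0, seed = 1) {
  t <- seq(0, duration, by = 1 / fs)
  set.seed(seed)
  vals <- base * (1 + depth * cos(2 * pi * t / period)) + rnorm(length(t), 0, noise_sd)
  quick_rate(pmax(vals, 0), fs = fs)
}

# small complete synthetic session for round-trip / pipeline tests
tiny_session <- function(seed = 1, duration = 60) {
  cfg <- preset("naive", seed = seed, duration = duration)
  cfg$fs_lfp <- 200  # keep LFP small for I/O tests
  generate_session(cfg)
}

# LC train with evoked components over a 50-pulse meningeal train,
# using the naive preset's background dynamics
lc_evoked_train <- function(seed = 1, spec = NULL, n_stim = 50) {
  cfg <- preset("naive", seed = seed, duration = 30 + (n_stim - 1) * 2 + 30)
  if (is.null(spec)) spec <- cfg$evoked$LC
  ev <- stim_train(30, n_stim, "meningeal")
  tr <- sample_spikes(rate_process(cfg, "LC"), seed = seed + 5000,
                      region = "LC", unit_kind = "MUA", id = "LC_MUA")
  list(train = add_evoked(tr, ev, spec, seed = seed + 9000, baseline_rate = 15),
       events = ev, spec = spec)
}
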