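# Synthetic-session generator: presets, rate processes, Poisson
# sampling, evoked superposition, LFP pairs, and whole-session assembly.

test_that("presets encode the condition-defining parameters", {
  naive <- preset("naive", seed = 1)
  expect_equal(naive$coupling_lag, 0.0101)
  expect_equal(naive$rhythms$LC$slow$period, 400.4)
  expect_equal(naive$rhythms$LC$intermediate$period, 21.3)
  expect_equal(naive$evoked$LC$peak_latency, c(0.0628, 0.1296))

  sens <- preset("sensitized", seed = 1)
  expect_equal(sens$rhythms$LC$slow$period, 675.0)
  expect_equal(sens$rhythms$LC$intermediate$period, 20.5)
  expect_gt(sens$base_rate[["TCC"]], naive$base_rate[["TCC"]])
  expect_gt(sens$tcc_phase_advance, 0)
  expect_equal(sens$evoked$LC$gain[2], naive$evoked$LC$gain[2] * 0.3)

  prop <- preset("propranolol", seed = 1)
  expect_lt(prop$rhythms$LC$delta$depth, naive$rhythms$LC$delta$depth)
  expect_true(all(prop$evoked$LC$gain < naive$evoked$LC$gain))

  expect_identical(preset("naive", seed = 1), preset("naive", seed = 1))
  expect_error(preset("unknown"), "arg")
})

test_that("rate process reproduces the analytic envelope and shared shift", {
  cfg <- preset("naive", seed = 3, duration = 120)
  # all depths zero -> constant at base rate
  for (rg in c("LC", "TCC")) {
    cfg0 <- cfg
    cfg0$rhythms[[rg]] <- lapply(cfg0$rhythms[[rg]], function(r) {
      rhythm_spec(r$period, 0, r$phase0)
    })
    r <- rate_process(cfg0, rg)
    expect_equal(r$values, rep(cfg$base_rate[[rg]], length(r$values)))
  }
  # single rhythm, depth 1 -> min 0, max 2x base within discretisation
  cfg1 <- cfg
  cfg1$shared_fraction <- 1
  cfg1$rhythms$LC <- list(slow = rhythm_spec(10, 1))
  r <- rate_process(cfg1, "LC")
  expect_lt(min(r$values), 0.01 * cfg$base_rate[["LC"]])
  expect_equal(max(r$values), 2 * cfg$base_rate[["LC"]], tolerance = 1e-3)
  expect_true(all(r$values >= 0))

  # fully shared modulation: TCC rate is the LC rate delayed by the lag
  cfg2 <- preset("naive", seed = 4, duration = 120)
  cfg2$shared_fraction <- 1
  cfg2$coupling_lag <- 0.02  # one sample at fs_rate = 50
  cfg2$base_rate <- c(LC = 10, TCC = 10)
  rl <- rate_process(cfg2, "LC")
  rt <- rate_process(cfg2, "TCC")
  expect_lt(max(abs(rt$values[-1] - rl$values[-length(rl$values)])), 1e-6)
})

test_that("thinned spike trains have Poisson statistics", {
  # constant 0 -> empty
  expect_length(sample_spikes(quick_rate(rep(0, 100)), seed = 1), 0)
  # constant 20 Hz over 1000 s: counts within 4 sigma of 20000
  r <- quick_rate(rep(20, 2001), fs = 2)
  counts <- vapply(1:20, function(s) length(sample_spikes(r, s)), double(1))
  expect_true(all(abs(counts - 20000) < 4 * sqrt(20000)))
  expect_lt(abs(mean(counts) - 20000) / (sqrt(20000 / 20)), 4)
  # determinism
  expect_identical(sample_spikes(r, 7)$times, sample_spikes(r, 7)$times)
})

test_that("time-rescaled inter-spike intervals are unit exponential", {
  # inhomogeneous rate; rescale spikes by the cumulative intensity
  fs <- 100
  t <- seq(0, 500, by = 1 / fs)
  vals <- 10 * (1 + 0.8 * cos(2 * pi * t / 7))
  r <- quick_rate(vals, fs = fs)
  tr <- sample_spikes(r, seed = 42)
  cum <- cumsum(vals) / fs
  big_lambda <- approx(t, cum, xout = tr$times)$y
  u <- diff(big_lambda)
  ks <- ks.test(u, "pexp")
  expect_gt(ks$p.value, 0.01)
})

test_that("evoked superposition respects gain and recovers latencies", {
  base <- lc_evoked_train(seed = 1)
  tr0 <- sample_spikes(rate_process(preset("naive", seed = 1, duration = 100), "LC"),
                       seed = 2, region = "LC", unit_kind = "MUA")
  ev <- stim_train(10, 20, "meningeal")
  zero <- evoked_spec(0.05, 0.01, 0)
  expect_identical(add_evoked(tr0, ev, zero, seed = 3)$times, tr0$times)

  # a single strong component lands where configured
  one <- evoked_spec(0.0628, 0.010, 30)
  tr1 <- add_evoked(tr0, ev, one, seed = 4, baseline_rate = 15)
  p <- build_psth(tr1, ev)
  peak_bin <- which.max(p$rate)
  expect_lt(abs((p$bin_left[peak_bin] + p$bin_right[peak_bin]) / 2 - 0.0628), 0.01)

  # components extending beyond the ISI are rejected
  expect_error(add_evoked(tr0, ev, evoked_spec(1.99, 0.05, 5), seed = 5),
               "beyond the inter-stimulus interval")

  # the two LC components produce two distinct PSTH responses
  cmp <- extract_components(build_psth(base$train, base$events), "LC")
  expect_setequal(intersect(cmp$kind, c("early", "late")), c("early", "late"))
})

test_that("synthetic LFP pairs carry the configured delay and band content", {
  cfg <- preset("naive", seed = 6, duration = 60)
  cfg$lfp_noise_sd <- 0
  cfg$coupling_lag <- 0
  expect_equal(make_lfp(cfg, "LC")$values, make_lfp(cfg, "TCC")$values,
               tolerance = 1e-9)

  cfg$coupling_lag <- 0.0101
  lc <- make_lfp(cfg, "LC"); tcc <- make_lfp(cfg, "TCC")
  lag_samples <- as.numeric(crosscorrelogram_lag(lc, tcc, 0.2,
                                                 interpolate = FALSE)) * cfg$fs_lfp
  expect_lte(abs(lag_samples - 10), 1)

  # depth 0 -> white noise only: delta fraction of total power is small
  cfg0 <- preset("naive", seed = 7, duration = 120)
  cfg0$shared_fraction <- 0
  cfg0$rhythms$LC <- lapply(cfg0$rhythms$LC, function(r) rhythm_spec(r$period, 0))
  noise_lfp <- make_lfp(cfg0, "LC")
  p <- Mod(fft(noise_lfp$values - mean(noise_lfp$values)))^2
  freqs <- (seq_along(p) - 1) * cfg0$fs_lfp / length(p)
  pos <- freqs > 0 & freqs <= cfg0$fs_lfp / 2
  ratio <- sum(p[pos & freqs >= 0.3 & freqs <= 2]) / sum(p[pos])
  expect_lt(ratio, 0.1)
})

test_that("generated sessions are valid, deterministic and rate-conserving", {
  s <- generate_session(preset("naive", seed = 8, duration = 60), lfp = FALSE)
  expect_s3_class(s, "session")
  expect_identical(s$spike_trains$LC_MUA$unit_kind, "MUA")
  expect_identical(s$spike_trains$TCC_SU$unit_kind, "SU")
  expect_false(is.null(s$ground_truth))

  s2 <- generate_session(preset("naive", seed = 8, duration = 60), lfp = FALSE)
  expect_identical(s$spike_trains$LC_MUA$times, s2$spike_trains$LC_MUA$times)
  expect_identical(s$spike_trains$TCC_SU$times, s2$spike_trains$TCC_SU$times)

  # empirical LC spike count within 3 sigma of the rate-process integral
  cfg <- preset("naive", seed = 9, duration = 400)
  long <- generate_session(cfg, events = list(), lfp = FALSE)
  n <- length(long$spike_trains$LC_MUA$times)
  expected <- mean(rate_process(cfg, "LC")$values) * cfg$duration
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})
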