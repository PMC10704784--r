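# Delta-power ratios, synchronization index, LFP decimation,
# spectrogram, band-power time course, sliding R^2 and lag estimation.

test_that("delta power ratio localises band content", {
  t <- seq(0, 120, by = 0.02)
  in_band <- quick_rate(10 + 3 * sin(2 * pi * 1 * t), fs = 50)
  out_band <- quick_rate(10 + 3 * sin(2 * pi * 5 * t), fs = 50)
  expect_gt(delta_power_ratio(in_band), 0.95)
  expect_lt(delta_power_ratio(out_band), 0.05)

  # white noise: flat spectrum puts (2 - 0.3)/25 of AC power in band
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    delta_power_ratio(quick_rate(10 + rnorm(3001), fs = 50))
  }, double(1))
  expect_gt(mean(ratios), 0.068 * 0.5)
  expect_lt(mean(ratios), 0.068 * 1.5)

  # bounds and scale invariance
  expect_true(all(ratios >= 0 & ratios <= 1))
  set.seed(30)
  x <- quick_rate(10 + rnorm(3001), fs = 50)
  y <- quick_rate(2 + 7 * x$values, fs = 50)
  expect_equal(delta_power_ratio(x), delta_power_ratio(y), tolerance = 1e-12)

  expect_warning(rc <- delta_power_ratio(quick_rate(rep(5, 3001), fs = 50)),
                 "constant")
  expect_true(is.na(rc))
  expect_error(delta_power_ratio(quick_rate(rnorm(3001), fs = 50), c(0, 20)),
               "delta cycles")
})

test_that("sync index uses two inter-train windows and tracks delta depth", {
  trains <- list(stim_train(30, 50, "cutaneous"),
                 stim_train(800, 50, "meningeal"),
                 stim_train(1600, 50, "meningeal"))
  make_rate <- function(depth, seed) {
    set.seed(seed)
    t <- seq(0, 1800, by = 0.02)
    quick_rate(pmax(10 * (1 + depth * cos(2 * pi * t / 0.87)) +
                      rnorm(length(t), 0, 2), 0), fs = 50)
  }
  hi <- sync_index(make_rate(0.8, 1), trains)
  lo <- sync_index(make_rate(0.1, 1), trains)
  expect_equal(nrow(hi), 2)
  expect_true(all(hi$window_end - hi$window_start == 600))
  expect_gt(sync_value(hi), sync_value(lo))
  # windows sit strictly between trains
  gaps <- rbind(c(30 + 49 * 1.5 + 1.5, 800), c(800 + 49 * 2 + 2, 1600))
  expect_true(all(hi$window_start >= gaps[, 1] & hi$window_end <= gaps[, 2]))

  expect_error(sync_index(make_rate(0.5, 2), trains[1:2]), "gaps")
})

test_that("LFP decimation preserves the passband and rejects the stopband", {
  t <- seq(0, 20, by = 1e-3)
  tone1 <- uniform_signal(sin(2 * pi * 1 * t), fs = 1000, kind = "lfp_raw")
  d1 <- decimate_lfp(tone1)
  expect_equal(d1$fs, 50)
  mid <- d1$values[signal_times(d1) > 2 & signal_times(d1) < 18]
  expect_lt(abs(max(mid) - 1), 0.01)

  tone40 <- uniform_signal(sin(2 * pi * 40 * t), fs = 1000, kind = "lfp_raw")
  d40 <- decimate_lfp(tone40)
  expect_lt(max(abs(d40$values)), 10^(-20 / 20))

  const <- uniform_signal(rep(3, 5000), fs = 1000, kind = "lfp_raw")
  expect_equal(decimate_lfp(const)$values, rep(3, 250), tolerance = 1e-9)

  # zero-phase: a propagated impulse stays within one output sample
  imp <- rep(0, 20001); imp[10001] <- 1
  di <- decimate_lfp(uniform_signal(imp, fs = 1000, kind = "lfp_raw"))
  t_peak <- signal_times(di)[which.max(abs(di$values))]
  expect_lt(abs(t_peak - 10), 1 / 50)

  expect_error(decimate_lfp(uniform_signal(rnorm(100), fs = 50, kind = "lfp_raw")),
               ">= 100")
})

test_that("spectrogram has the stated resolution and localises tones", {
  t <- seq(0, 120, by = 0.02)
  tone <- uniform_signal(sin(2 * pi * 1 * t), fs = 50, kind = "lfp_decimated")
  sg <- spectrogram(tone)
  expect_equal(diff(sg$freqs)[1], 50 / 8096, tolerance = 1e-12)
  ridge <- sg$freqs[apply(sg$log_psd, 2, which.max)]
  expect_lt(max(abs(ridge - 1)), 50 / 8096 * 2)

  # white noise: flat log-PSD within estimator variance
  set.seed(12)
  wn <- uniform_signal(rnorm(6001), fs = 50, kind = "lfp_decimated")
  sgw <- spectrogram(wn)
  band_means <- tapply(rowMeans(sgw$log_psd),
                       cut(sgw$freqs, breaks = seq(0, 25, by = 5)), mean)
  expect_lt(max(band_means) - min(band_means), 1)

  expect_error(spectrogram(uniform_signal(rnorm(500), fs = 50,
                                          kind = "lfp_decimated")),
               "1024")
})

test_that("delta-band time course tracks amplitude modulation", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  envelope <- 1 + 0.8 * sin(2 * pi * t / 150)
  am <- uniform_signal(envelope * sin(2 * pi * 1 * t), fs = fs,
                       kind = "lfp_decimated")
  tc <- delta_band_timecourse(spectrogram(am))
  env_at <- approx(t, envelope, xout = signal_times(tc))$y
  expect_gt(cor(tc$values, env_at), 0.9)

  # stationary tone: near-constant time course
  st <- uniform_signal(sin(2 * pi * 1 * t) + 1e-3 * rnorm(length(t)), fs = fs,
                       kind = "lfp_decimated")
  tcs <- delta_band_timecourse(spectrogram(st))
  expect_lt(sd(tcs$values) / abs(mean(tcs$values)), 0.05)

  # out-of-band tone sits at the noise floor, below the in-band tone
  hi <- uniform_signal(sin(2 * pi * 5 * t) + 1e-3 * rnorm(length(t)), fs = fs,
                       kind = "lfp_decimated")
  tch <- delta_band_timecourse(spectrogram(hi))
  expect_lt(mean(tch$values), mean(tcs$values))
})

test_that("sliding R^2 is bounded, affine invariant and calibrated", {
  fs <- 5
  t <- seq(0, 800, by = 1 / fs)
  set.seed(13)
  x <- uniform_signal(10 + 3 * sin(2 * pi * t / 200) + rnorm(length(t), 0, 0.2),
                      fs = fs, kind = "band_power")
  same <- sliding_r2(x, uniform_signal(x$values, fs, kind = "rate"))
  expect_equal(same$r2max, 1, tolerance = 1e-9)

  # affine transforms leave R^2 unchanged
  aff <- sliding_r2(x, uniform_signal(5 - 2.5 * x$values, fs, kind = "rate"))
  expect_equal(aff$r2max, 1, tolerance = 1e-9)

  # independent white noise: small r2max
  r2n <- vapply(1:10, function(s) {
    set.seed(100 + s)
    a <- uniform_signal(rnorm(length(t)), fs, kind = "band_power")
    b <- uniform_signal(rnorm(length(t)), fs, kind = "rate")
    sliding_r2(a, b)$r2max
  }, double(1))
  expect_lt(mean(r2n), 0.2)

  expect_error(sliding_r2(uniform_signal(rnorm(100), 5, kind = "band_power"),
                          uniform_signal(rnorm(100), 5, kind = "rate")),
               "400")
})

test_that("cross-correlogram lag finds shifts with exact antisymmetry", {
  set.seed(14)
  x <- rnorm(6000)
  a <- uniform_signal(x[11:5010], 1000, kind = "lfp_raw")
  b <- uniform_signal(x[1:5000], 1000, kind = "lfp_raw")

  expect_equal(as.numeric(crosscorrelogram_lag(a, a, 0.05)), 0)
  expect_equal(as.numeric(crosscorrelogram_lag(a, b, 0.05, interpolate = FALSE)),
               0.010)
  l1 <- as.numeric(crosscorrelogram_lag(a, b, 0.05))
  l2 <- as.numeric(crosscorrelogram_lag(b, a, 0.05))
  expect_equal(l1, 0.010, tolerance = 2e-4)
  expect_equal(l1 + l2, 0)

  expect_warning(lc <- crosscorrelogram_lag(
    uniform_signal(rep(1, 1000), 1000, kind = "lfp_raw"), b, 0.05), "constant")
  expect_true(is.na(lc))
  expect_error(crosscorrelogram_lag(a, uniform_signal(x[1:5000], 500,
                                                      kind = "lfp_raw")),
               "sampling rate")
})
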