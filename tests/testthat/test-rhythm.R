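# Mean frequency, period estimation, instantaneous phase, spike-phase
# histograms and precession.

test_that("mean frequency matches analytic counts", {
  # regular 10 Hz train: interior samples at 10 Hz within 1/width
  tr <- spike_train(seq(0.05, 99.95, by = 0.1), "LC", "MUA")
  mf <- mean_frequency(tr, width = 1, fs_out = 2, t_end = 100)
  interior <- signal_times(mf) > 2 & signal_times(mf) < 98
  expect_true(all(abs(mf$values[interior] - 10) <= 1 + 1e-9))

  # empty train -> zeros
  mf0 <- mean_frequency(spike_train(numeric(), "LC", "MUA"), 1, 2, t_end = 10)
  expect_true(all(mf0$values == 0))

  # single spike: peak of 1 Hz at the spike, zero far away
  mf1 <- mean_frequency(spike_train(5, "LC", "MUA"), 1, 10, t_end = 10)
  expect_equal(mf1$values[signal_times(mf1) == 5], 1)
  expect_equal(mf1$values[signal_times(mf1) == 9], 0)
})

test_that("period estimation recovers injected periods", {
  # intermediate rhythm at the naive period
  r <- sine_rate(21.3, 1200, fs = 2, noise_sd = 0.5, seed = 2)
  p <- estimate_period(r, "intermediate")
  expect_lt(abs(p - 21.3) / 21.3, 0.05)

  # two superimposed rhythms; the slow band isolates the slow one
  t <- seq(0, 4000, by = 0.5)
  set.seed(3)
  vals <- 10 + 4 * cos(2 * pi * t / 400) + 3 * cos(2 * pi * t / 21) +
    rnorm(length(t), 0, 0.5)
  r2 <- quick_rate(pmax(vals, 0), fs = 2)
  expect_lt(abs(estimate_period(r2, "slow") - 400) / 400, 0.1)
  expect_lt(abs(estimate_period(r2, "intermediate") - 21) / 21, 0.05)

  # white noise: flagged low-confidence
  set.seed(4)
  rn <- quick_rate(10 + rnorm(2401), fs = 2)
  expect_warning(pn <- estimate_period(rn, "intermediate"), "low-confidence")
  expect_true(is.na(pn))

  # invariance to amplitude scaling and offsets (up to filter round-off)
  r3 <- quick_rate(3 + 5 * r$values, fs = 2)
  expect_equal(as.numeric(estimate_period(r3, "intermediate")), as.numeric(p),
               tolerance = 1e-4)

  expect_error(estimate_period(sine_rate(21.3, 60), "slow"), "at least")
})

test_that("instantaneous phase follows the cosine convention", {
  t <- seq(0, 1200, by = 0.5)
  cosr <- quick_rate(10 + 3 * cos(2 * pi * t / 21.3), fs = 2)
  ph <- instantaneous_phase(cosr, "intermediate")
  times <- signal_times(ph)
  ok <- times > attr(ph, "valid_from") & times < attr(ph, "valid_to")
  expected <- wrap_phase(2 * pi * times / 21.3)
  err <- wrap_phase(ph$values - expected)
  expect_lt(max(abs(err[ok])), 0.1)

  sinr <- quick_rate(10 + 3 * sin(2 * pi * t / 21.3), fs = 2)
  ph2 <- instantaneous_phase(sinr, "intermediate")
  mid <- which.min(abs(times - 21.3 * 20))  # away from edges, phase ~ t - pi/2
  expect_lt(abs(wrap_phase(ph2$values[mid] - (2 * pi * times[mid] / 21.3 - pi / 2))),
            0.1)

  expect_error(instantaneous_phase(quick_rate(rnorm(100), fs = 2), "delta"),
               "Nyquist")
})

test_that("phase histograms are z-scored with circular-mean preferred phase", {
  # uniform spikes -> flat z profile (fixed seed, n = 8000)
  t <- seq(0, 4000, by = 0.5)
  ph <- uniform_signal(wrap_phase(2 * pi * t / 21.3), fs = 2, kind = "phase")
  set.seed(5)
  tru <- spike_train(sort(unique(runif(8000, 0, 4000))), "LC", "MUA")
  h <- phase_histogram(tru, ph, 150)
  expect_equal(mean(h$z), 0, tolerance = 1e-9)
  expect_equal(sd(h$z), 1, tolerance = 1e-9)
  expect_lt(max(abs(h$z)), 3.8)
  expect_equal(sum(h$count), attr(h, "n_spikes"))

  # all spikes at phase 0: one loaded bin, preferred 0 (20 s period so
  # spike times sit exactly on phase samples)
  ph20 <- uniform_signal(wrap_phase(2 * pi * t / 20), fs = 2, kind = "phase")
  spikes0 <- seq(20, 3900, by = 20)
  h0 <- phase_histogram(spike_train(spikes0, "LC", "MUA"), ph20, 75)
  expect_equal(max(h0$count), attr(h0, "n_spikes"))
  expect_lt(abs(preferred_phase(h0)), 0.05)

  # cosine-modulated train recovers the modulation peak
  r <- sine_rate(21.3, 4000, fs = 10, base = 6, depth = 0.8, seed = 6)
  trc <- sample_spikes(r, seed = 7)
  phc <- uniform_signal(wrap_phase(2 * pi * signal_times(r) / 21.3), fs = 10,
                        kind = "phase")
  hc <- phase_histogram(trc, phc, 150)
  expect_lt(abs(preferred_phase(hc)), 0.15)

  expect_error(phase_histogram(tru, ph, 100), "75 or 150")
})

test_that("precession is the wrapped circular difference", {
  t <- seq(0, 4000, by = 0.5)
  ph <- uniform_signal(wrap_phase(2 * pi * t / 21.3), fs = 2, kind = "phase")
  set.seed(8)
  base_times <- sort(unique(runif(4000, 100, 3900)))
  h1 <- phase_histogram(spike_train(base_times, "LC", "MUA"), ph, 150)
  expect_equal(as.numeric(precession(h1, h1)), 0)

  # constructed +pi/4 shift: delay TCC spikes by an eighth of a cycle
  shift <- (pi / 4) / (2 * pi) * 21.3
  mod_times <- sort(unique(c(seq(21.3, 3800, by = 21.3))))
  h_lc <- phase_histogram(spike_train(mod_times, "LC", "MUA"), ph, 150)
  h_tcc <- phase_histogram(spike_train(mod_times + shift, "TCC", "SU"), ph, 150)
  expect_lt(abs(as.numeric(precession(h_tcc, h_lc)) - pi / 4), 0.1)

  h75 <- phase_histogram(spike_train(mod_times, "LC", "MUA"), ph, 75)
  expect_error(precession(h75, h1), "different bin counts")
})

test_that("constructed phase advances are recovered through the full pipeline", {
  recover <- function(offset, seed) {
    cfg <- preset("naive", seed = seed, duration = 600)
    cfg$tcc_phase_advance <- offset
    cfg$phase_advance_rhythm <- "intermediate"
    cfg$shared_fraction <- 1
    s <- generate_session(cfg, events = list(), lfp = FALSE)
    lc <- session_trains(s, "LC")[[1]]
    tcc <- session_trains(s, "TCC")[[1]]
    ref <- instantaneous_phase(mean_frequency(lc, 10, 2, t_end = 600),
                               "intermediate")
    as.numeric(precession(phase_histogram(tcc, ref), phase_histogram(lc, ref)))
  }
  est <- sapply(1:20, function(s) recover(pi / 8, s))
  expect_lt(mean(abs(est - pi / 8)), 0.15)
  expect_lt(abs(mean(est) - pi / 8), 0.1)
})
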