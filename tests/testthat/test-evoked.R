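# PSTH construction, the tail-referenced evoked-bin criterion, component
# extraction, A/C train counts and the LC/TCC evoked ratio.

test_that("PSTH bins spikes by hand-countable offsets", {
  ev <- event_series(c(0, 1.5), 8e-4, 1.5, "cutaneous")
  tr <- spike_train(c(0.010, 1.510), "TCC", "SU")
  p <- build_psth(tr, ev, bin_width = 0.001)
  expect_equal(attr(p, "n_stim"), 2)
  expect_equal(p$count[p$bin_left == 0.010], 2L)
  expect_equal(sum(p$count), 2L)
  expect_equal(p$rate, p$count / (2 * 0.001))

  # empty train
  p0 <- build_psth(spike_train(numeric(), "TCC", "SU"), ev)
  expect_true(all(p0$count == 0))
  expect_equal(attr(p0, "tail_mean"), 0)

  expect_error(build_psth(tr, event_series(0.5, 8e-4, 1.5, "cutaneous")),
               "at least 2")
  expect_error(build_psth(tr, ev, window = 2), "inter-stimulus")
  expect_error(build_psth(tr, ev, bin_width = 0.0007), "divide")
})

test_that("PSTH count conservation holds over random trains", {
  for (s in 1:5) {
    set.seed(s)
    ev <- stim_train(5, 20, "meningeal")
    times <- sort(runif(500, 0, 60))
    tr <- spike_train(unique(times), "LC", "MUA")
    p <- build_psth(tr, ev, bin_width = 0.002)
    idx <- findInterval(tr$times, ev$onsets)
    offs <- tr$times[idx >= 1] - ev$onsets[pmax(idx[idx >= 1], 1)]
    expect_equal(sum(p$count), sum(offs >= 0 & offs < 2))
  }
})

test_that("evoked-bin criterion is literal, strict and scale invariant", {
  # rates [10, 0, 0, 0] with the tail covering the last two bins
  ev <- event_series(c(0, 1), 5e-3, 1, "meningeal", regular = FALSE)
  tr <- spike_train(c(0.1, 1.1), "LC", "MUA")
  p <- build_psth(tr, ev, window = 1, bin_width = 0.25)
  expect_equal(detect_evoked_bins(p), c(TRUE, FALSE, FALSE, FALSE))

  # uniform PSTH: equality fails the strict criterion
  tru <- spike_train(seq(0.125, 1.875, by = 0.25), "LC", "MUA")
  evu <- event_series(c(0, 2), 5e-3, 2, "meningeal", regular = FALSE)
  pu <- build_psth(tru, evu, window = 2, bin_width = 0.25)
  expect_true(all(pu$count == 1L))
  expect_false(any(detect_evoked_bins(pu)))

  # all-zero PSTH
  p0 <- build_psth(spike_train(numeric(), "LC", "MUA"), evu, window = 2,
                   bin_width = 0.25)
  expect_false(any(detect_evoked_bins(p0)))

  # invariance under uniform rescaling (same spikes, more stimuli per spike)
  set.seed(11)
  ev1 <- stim_train(5, 25, "meningeal")
  tr1 <- spike_train(unique(sort(runif(400, 0, 60))), "LC", "MUA")
  p1 <- build_psth(tr1, ev1, bin_width = 0.01)
  scaled <- p1
  scaled$rate <- p1$rate * 3.7
  attr(scaled, "tail_mean") <- attr(p1, "tail_mean") * 3.7
  expect_identical(detect_evoked_bins(scaled), detect_evoked_bins(p1))
})

test_that("TCC components classify by the 30 ms boundary", {
  # single clean run peaking at 12 ms -> one A component
  ev <- stim_train(1, 30, "cutaneous")
  offs <- rep(c(0.011, 0.012, 0.013), each = 30)
  tr <- spike_train(sort(unique(rep(ev$onsets, 3) + offs)), "TCC", "SU")
  p <- build_psth(tr, ev, bin_width = 0.001)
  cmp <- extract_components(p, "TCC")
  expect_equal(nrow(cmp), 1)
  expect_identical(cmp$kind, "A")
  expect_lt(abs(cmp$time_to_peak - 0.012), 0.003)

  # empty mask -> empty component table
  p0 <- build_psth(spike_train(numeric(), "TCC", "SU"), ev)
  expect_equal(nrow(extract_components(p0, "TCC")), 0)

  # a run straddling 30 ms is split into A and C parts
  offs2 <- seq(0.026, 0.040, by = 0.001)
  tr2 <- spike_train(sort(unique(as.vector(outer(ev$onsets, offs2, "+")))),
                     "TCC", "SU")
  cmp2 <- extract_components(build_psth(tr2, ev, bin_width = 0.001), "TCC")
  expect_setequal(cmp2$kind, c("A", "C"))
  expect_true(all(cmp2$run_end[cmp2$kind == "A"] <= 30))
})

test_that("LC early/late latencies are recovered from synthetic trains", {
  errs <- sapply(1:6, function(s) {
    made <- lc_evoked_train(seed = s)
    cmp <- extract_components(build_psth(made$train, made$events), "LC")
    c(early = cmp$time_to_peak[cmp$kind == "early"] - 0.0628,
      late = cmp$time_to_peak[cmp$kind == "late"] - 0.1296)
  })
  expect_lt(mean(abs(errs["early", ])), 0.002)
  expect_lt(mean(abs(errs["late", ])), 0.002)
  expect_lt(max(abs(errs)), 0.006)
})

test_that("A/C train counts follow the half-open window rule", {
  ev <- stim_train(0, 50, "meningeal")
  # one spike at 10 ms offset after every stimulus
  tr <- spike_train(ev$onsets + 0.010, "TCC", "SU")
  counts <- tcc_train_counts(tr, ev)
  expect_equal(counts$A_total, 50)
  expect_equal(counts$C_total, 0)

  expect_equal(tcc_train_counts(spike_train(numeric(), "TCC", "SU"), ev),
               tibble::tibble(A_total = 0L, C_total = 0L),
               ignore_attr = TRUE)

  # boundary: a spike at exactly 30 ms is C, not A
  tr30 <- spike_train(ev$onsets[1] + 0.030, "TCC", "SU")
  c30 <- tcc_train_counts(tr30, ev)
  expect_equal(c30$A_total, 0)
  expect_equal(c30$C_total, 1)

  short <- event_series(seq(0, by = 0.1, length.out = 5), 5e-3, 0.1,
                        "meningeal", regular = FALSE)
  expect_error(tcc_train_counts(tr, short), "overlap")
})

test_that("LC/TCC evoked ratio is percent magnitude per A spike", {
  expect_equal(lc_tcc_evoked_ratio(list(magnitude = 2.0), 100), 2.0)
  expect_equal(lc_tcc_evoked_ratio(list(magnitude = 0), 50), 0)
  expect_warning(r <- lc_tcc_evoked_ratio(list(magnitude = 1), 0), "zero")
  expect_true(is.na(r))

  # propranolol scales the LC gains down: the ratio drops against the
  # same TCC denominator
  ratio_for <- function(cond, s) {
    cfg <- preset(cond, seed = s, duration = 200)
    made <- lc_evoked_train(seed = s, spec = cfg$evoked$LC)
    cmp <- extract_components(build_psth(made$train, made$events), "LC")
    mag <- cmp$magnitude[cmp$kind == "early"]
    lc_tcc_evoked_ratio(list(magnitude = mag), 100)
  }
  ratios <- sapply(1:5, function(s) c(naive = ratio_for("naive", s),
                                      prop = ratio_for("propranolol", s)))
  expect_true(all(ratios["prop", ] < ratios["naive", ]))
})
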