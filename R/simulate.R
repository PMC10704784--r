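# Synthetic two-region session generator: multi-timescale modulated
# inhomogeneous-Poisson spiking, shared delta-band LFP drive with a
# directed LC -> TCC lag, stimulus-evoked Gaussian components, and
# condition presets. Every downstream stage is validated by recovering
# what this module injects.

#' Oscillatory rhythm specification
#'
#' One multiplicative rhythm of the firing-rate process: the rate is
#' modulated by `1 + depth * cos(2 * pi * t / period + phase0)`.
#'
#' @param period oscillation period in seconds (> 0).
#' @param depth modulation depth in \[0, 1\].
#' @param phase0 phase at t = 0, radians.
#' @return list of class `rhythm_spec`.
#' @examples
#' rhythm_spec(period = 21.3, depth = 0.5)
#' @export
rhythm_spec <- function(period, depth, phase0 = 0) {
  stopifnot_scalar_number(period, "period")
  stopifnot_scalar_number(depth, "depth")
  stopifnot_scalar_number(phase0, "phase0")
  if (period <= 0) abort("`period` must be > 0.")
  if (depth < 0 || depth > 1) abort("`depth` must be in [0, 1].")
  structure(list(period = period, depth = depth, phase0 = phase0),
            class = "rhythm_spec")
}

#' Evoked-response specification
#'
#' Stimulus-locked response components, each a Gaussian bump of extra
#' firing rate centred at `peak_latency` with standard deviation `width`
#' and a multiplicative `gain` relative to the baseline rate: the extra
#' rate at the peak is `gain * baseline`.
#'
#' @param peak_latency post-stimulus peak latencies in seconds, positive,
#'   strictly increasing.
#' @param width Gaussian widths (sd) in seconds, > 0.
#' @param gain dimensionless rate boosts, >= 0.
#' @return tibble of class `evoked_spec` with one row per component.
#' @examples
#' evoked_spec(peak_latency = c(0.0628, 0.1296), width = c(0.010, 0.012),
#'             gain = c(8, 6))
#' @export
evoked_spec <- function(peak_latency, width, gain) {
  if (length(peak_latency) == 0) {
    return(structure(tibble::tibble(peak_latency = double(), width = double(),
                                    gain = double()),
                     class = c("evoked_spec", "tbl_df", "tbl", "data.frame")))
  }
  if (any(peak_latency <= 0)) abort("`peak_latency` must be positive.")
  if (length(peak_latency) > 1 && any(diff(peak_latency) <= 0)) {
    abort("`peak_latency` must be strictly increasing.")
  }
  if (any(width <= 0)) abort("`width` must be > 0.")
  if (any(gain < 0)) abort("`gain` must be >= 0.")
  out <- tibble::tibble(peak_latency = as.double(peak_latency),
                        width = as.double(width), gain = as.double(gain))
  class(out) <- c("evoked_spec", class(out))
  out
}

#' Generator configuration for synthetic coupled sessions
#'
#' Full parameterisation of a synthetic two-region session. The two
#' regions share a fraction `shared_fraction` of their rate modulation;
#' the TCC copy of every shared component is delayed by `coupling_lag`
#' (positive = LC leads). `tcc_phase_advance` shifts the preferred phase
#' of the TCC on the shared cycle of one rhythm (`phase_advance_rhythm`),
#' the generative counterpart of the phase precession seen after
#' sensitization.
#'
#' @param duration session duration, seconds.
#' @param base_rate named numeric `c(LC = , TCC = )`, mean rates in Hz.
#' @param rhythms named list (`LC`, `TCC`), each a named list of
#'   [rhythm_spec()] (conventionally `slow`, `intermediate`, `delta`).
#' @param coupling_lag directed LC -> TCC delay in seconds.
#' @param shared_fraction fraction of rate modulation common to both
#'   regions, in \[0, 1\].
#' @param evoked named list (`LC`, `TCC`) of [evoked_spec()].
#' @param tcc_phase_advance radians by which the TCC preferred phase is
#'   shifted on the shared cycle (recovered as-is by [precession()]).
#' @param phase_advance_rhythm which rhythm the advance applies to.
#' @param lfp_noise_sd sd of white measurement noise added to the LFP,
#'   in units of the unit-variance delta drive.
#' @param fs_lfp LFP sampling rate, Hz (must exceed twice the delta upper
#'   edge of 2 Hz).
#' @param fs_rate sampling rate of the generated rate processes, Hz.
#' @param n_subtrains number of independently thinned trains merged into
#'   the LC multi-unit cluster.
#' @param n_stim pulses per electrical stimulation train.
#' @param condition condition label attached to generated sessions.
#' @param seed master seed; every random stream in the generator derives
#'   from it.
#' @return list of class `generator_config`.
#' @seealso [preset()] for the condition presets.
#' @export
generator_config <- function(duration,
                             base_rate = c(LC = 15, TCC = 2),
                             rhythms,
                             coupling_lag = 0.0101,
                             shared_fraction = 0.8,
                             evoked = list(LC = evoked_spec(double(), double(), double()),
                                           TCC = evoked_spec(double(), double(), double())),
                             tcc_phase_advance = 0,
                             phase_advance_rhythm = "slow",
                             lfp_noise_sd = 0.3,
                             fs_lfp = 1000,
                             fs_rate = 50,
                             n_subtrains = 4,
                             n_stim = 50,
                             condition = "naive",
                             seed = 1) {
  stopifnot_scalar_number(duration, "duration")
  if (duration <= 0) abort("`duration` must be > 0.")
  if (!all(c("LC", "TCC") %in% names(base_rate))) {
    abort("`base_rate` must be named with LC and TCC.")
  }
  if (any(base_rate < 0)) abort("base rates must be >= 0.")
  if (!all(c("LC", "TCC") %in% names(rhythms))) {
    abort("`rhythms` must be a named list with LC and TCC entries.")
  }
  for (rg in c("LC", "TCC")) {
    for (r in rhythms[[rg]]) {
      if (!inherits(r, "rhythm_spec")) abort("rhythms must be rhythm_spec objects.")
    }
    if (!inherits(evoked[[rg]], "evoked_spec")) {
      abort("evoked must be evoked_spec objects.")
    }
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1].")
  }
  if (fs_lfp < 2 * 2) abort("`fs_lfp` must be at least twice the 2 Hz delta upper edge.")
  structure(
    list(duration = duration, base_rate = base_rate, rhythms = rhythms,
         coupling_lag = coupling_lag, shared_fraction = shared_fraction,
         evoked = evoked, tcc_phase_advance = tcc_phase_advance,
         phase_advance_rhythm = phase_advance_rhythm,
         lfp_noise_sd = lfp_noise_sd, fs_lfp = fs_lfp, fs_rate = fs_rate,
         n_subtrains = as.integer(n_subtrains), n_stim = as.integer(n_stim),
         condition = condition, seed = as.double(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> '%s', %g s, seed %g\n", x$condition,
              x$duration, x$seed))
  cat(sprintf("  base rates LC %g Hz / TCC %g Hz, lag %g ms, shared %g\n",
              x$base_rate[["LC"]], x$base_rate[["TCC"]],
              1e3 * x$coupling_lag, x$shared_fraction))
  invisible(x)
}

# --- (de)serialisation of configs, used by session round trips ----------

config_to_list <- function(config) {
  list(
    duration = config$duration,
    base_rate = as.list(config$base_rate),
    rhythms = lapply(config$rhythms, function(rg) {
      lapply(rg, function(r) list(period = r$period, depth = r$depth,
                                  phase0 = r$phase0))
    }),
    coupling_lag = config$coupling_lag,
    shared_fraction = config$shared_fraction,
    evoked = lapply(config$evoked, function(ev) {
      list(peak_latency = ev$peak_latency, width = ev$width, gain = ev$gain)
    }),
    tcc_phase_advance = config$tcc_phase_advance,
    phase_advance_rhythm = config$phase_advance_rhythm,
    lfp_noise_sd = config$lfp_noise_sd,
    fs_lfp = config$fs_lfp,
    fs_rate = config$fs_rate,
    n_subtrains = config$n_subtrains,
    n_stim = config$n_stim,
    condition = config$condition,
    seed = config$seed
  )
}

config_from_list <- function(x) {
  generator_config(
    duration = x$duration,
    base_rate = c(LC = x$base_rate$LC, TCC = x$base_rate$TCC),
    rhythms = lapply(x$rhythms, function(rg) {
      lapply(rg, function(r) rhythm_spec(r$period, r$depth, r$phase0))
    }),
    coupling_lag = x$coupling_lag,
    shared_fraction = x$shared_fraction,
    evoked = lapply(x$evoked, function(ev) {
      evoked_spec(unlist(ev$peak_latency), unlist(ev$width), unlist(ev$gain))
    }),
    tcc_phase_advance = x$tcc_phase_advance,
    phase_advance_rhythm = x$phase_advance_rhythm,
    lfp_noise_sd = x$lfp_noise_sd,
    fs_lfp = x$fs_lfp,
    fs_rate = x$fs_rate,
    n_subtrains = x$n_subtrains,
    n_stim = x$n_stim,
    condition = x$condition,
    seed = x$seed
  )
}

#' Condition presets for the generator
#'
#' Fully populated [generator_config()]s encoding the three study
#' conditions:
#'
#' * `naive` — slow / intermediate rhythm periods of 400.4 s and 21.3 s,
#'   a 1 Hz delta rhythm, LC leading the TCC by 10.1 ms, and LC evoked
#'   components peaking 62.8 ms and 129.6 ms post-stimulus.
#' * `sensitized` — slow / intermediate periods of 675.0 s and 20.5 s,
#'   TCC baseline rate raised three-fold, a positive TCC phase advance on
#'   the slow rhythm, and the LC late evoked component scaled to 0.3 of
#'   its naive gain.
#' * `propranolol` — naive rhythms but the LC delta-rhythm depth scaled
#'   to 0.3 and LC evoked gains to 0.4 of their naive values (reduced LC
#'   synchronization and responsiveness after the microinjection).
#'
#' @param condition `"naive"`, `"sensitized"` or `"propranolol"`.
#' @param seed master seed passed through to the config.
#' @param duration session duration in seconds.
#' @return a [generator_config()].
#' @examples
#' preset("naive", seed = 1)$coupling_lag
#' @export
preset <- function(condition = c("naive", "sensitized", "propranolol"),
                   seed = 1, duration = 600) {
  condition <- match.arg(condition)

  naive_rhythms <- function() {
    list(
      slow = rhythm_spec(period = 400.4, depth = 0.6),
      intermediate = rhythm_spec(period = 21.3, depth = 0.5),
      delta = rhythm_spec(period = 0.87, depth = 0.4)
    )
  }
  lc_evoked <- evoked_spec(peak_latency = c(0.0628, 0.1296),
                           width = c(0.010, 0.012), gain = c(8, 6))
  tcc_evoked <- evoked_spec(peak_latency = c(0.012, 0.080),
                            width = c(0.003, 0.020), gain = c(60, 12))

  if (condition == "naive") {
    generator_config(
      duration = duration,
      base_rate = c(LC = 15, TCC = 2),
      rhythms = list(LC = naive_rhythms(), TCC = naive_rhythms()),
      coupling_lag = 0.0101,
      evoked = list(LC = lc_evoked, TCC = tcc_evoked),
      condition = "naive", seed = seed
    )
  } else if (condition == "sensitized") {
    sens_rhythms <- function() {
      list(
        slow = rhythm_spec(period = 675.0, depth = 0.6),
        intermediate = rhythm_spec(period = 20.5, depth = 0.5),
        delta = rhythm_spec(period = 0.87, depth = 0.4)
      )
    }
    lc_ev <- lc_evoked
    lc_ev$gain[2] <- lc_ev$gain[2] * 0.3
    generator_config(
      duration = duration,
      base_rate = c(LC = 15, TCC = 6),
      rhythms = list(LC = sens_rhythms(), TCC = sens_rhythms()),
      coupling_lag = 0.0101,
      evoked = list(LC = lc_ev, TCC = tcc_evoked),
      tcc_phase_advance = 0.5,
      phase_advance_rhythm = "slow",
      condition = "sensitized", seed = seed
    )
  } else {
    prop_lc <- naive_rhythms()
    prop_lc$delta <- rhythm_spec(period = 0.87, depth = 0.4 * 0.3)
    lc_ev <- lc_evoked
    lc_ev$gain <- lc_ev$gain * 0.4
    generator_config(
      duration = duration,
      base_rate = c(LC = 15, TCC = 2),
      rhythms = list(LC = prop_lc, TCC = naive_rhythms()),
      coupling_lag = 0.0101,
      evoked = list(LC = lc_ev, TCC = tcc_evoked),
      condition = "propranolol", seed = seed
    )
  }
}

#' Firing-rate process of one region
#'
#' Evaluates the modulated rate
#' `rate(t) = base * prod_r (1 + depth_r * m_r(t))`, clipped at zero,
#' where each rhythm's modulation mixes a shared component (common to
#' both regions, delayed by `coupling_lag` for the TCC) and a
#' region-specific component with an independent seeded phase, weighted
#' `shared_fraction` to `1 - shared_fraction`. The TCC's shared
#' modulation of the `phase_advance_rhythm` is additionally advanced so
#' that its peak sits `tcc_phase_advance` radians later on the shared
#' reference cycle (the convention recovered by [precession()]).
#'
#' @param config a [generator_config()].
#' @param region `"LC"` or `"TCC"`.
#' @return a rate-kind [uniform_signal()] sampled at `config$fs_rate`.
#' @export
rate_process <- function(config, region = c("LC", "TCC")) {
  region <- match.arg(region)
  stopifnot(inherits(config, "generator_config"))
  n <- max(2L, round(config$duration * config$fs_rate))
  t <- (seq_len(n) - 1) / config$fs_rate
  lag <- if (region == "TCC") config$coupling_lag else 0
  f <- config$shared_fraction

  rate <- rep(config$base_rate[[region]], n)
  specs <- config$rhythms[[region]]
  for (i in seq_along(specs)) {
    r <- specs[[i]]
    adv <- if (region == "TCC" &&
               identical(names(specs)[i], config$phase_advance_rhythm)) {
      config$tcc_phase_advance
    } else {
      0
    }
    shared_phase <- 2 * pi * (t - lag) / r$period + r$phase0
    m_shared <- cos(shared_phase - adv)
    own_phase0 <- with_local_seed(
      derive_seed(config$seed, 10 + i + 100 * (region == "TCC")),
      runif(1, -pi, pi)
    )
    m_own <- cos(2 * pi * t / r$period + own_phase0)
    rate <- rate * (1 + r$depth * (f * m_shared + (1 - f) * m_own))
  }
  uniform_signal(pmax(rate, 0), fs = config$fs_rate, t0 = 0, kind = "rate")
}

#' Sample a spike train from a rate signal
#'
#' Inhomogeneous-Poisson sampling by thinning against the maximum rate;
#' the rate between grid samples is linearly interpolated. Reproducible
#' given `seed`.
#'
#' @param rate a rate-kind [uniform_signal()] with non-negative values.
#' @param seed RNG seed.
#' @param region,unit_kind,id passed to [spike_train()].
#' @return a [spike_train()].
#' @export
sample_spikes <- function(rate, seed, region = "LC", unit_kind = "MUA",
                          id = "unit") {
  stopifnot(inherits(rate, "uniform_signal"))
  if (rate$kind != "rate") abort("`rate` must be a rate-kind signal.")
  if (any(rate$values < 0)) abort("rate values must be >= 0.")
  rmax <- max(rate$values)
  span <- signal_duration(rate)
  times <- double()
  if (rmax > 0 && span > 0) {
    times <- with_local_seed(seed, {
      n_cand <- rpois(1, rmax * span)
      cand <- sort(runif(n_cand, rate$t0, rate$t0 + span))
      keep <- runif(n_cand) < signal_at(rate, cand) / rmax
      cand[keep]
    })
    times <- unique(times)
  }
  spike_train(times, region = region, unit_kind = unit_kind, id = id)
}

#' Superimpose stimulus-evoked spikes on a spike train
#'
#' For every stimulus onset and every component of `spec`, extra spikes
#' are drawn from a Poisson count with mean
#' `gain * baseline * width * sqrt(2*pi)` (the integral of the Gaussian
#' rate bump) and placed at `Normal(peak_latency, width)` offsets;
#' samples falling outside the half-open `[0, isi)` window are dropped.
#' The original spikes are retained.
#'
#' @param train a [spike_train()].
#' @param events an [event_series()].
#' @param spec an [evoked_spec()].
#' @param seed RNG seed.
#' @param baseline_rate baseline rate in Hz used to scale the bumps;
#'   defaults to the train's mean rate over its span.
#' @return a [spike_train()] with the evoked spikes merged in.
#' @export
add_evoked <- function(train, events, spec, seed, baseline_rate = NULL) {
  stopifnot(inherits(train, "spike_train"), inherits(events, "event_series"),
            inherits(spec, "evoked_spec"))
  if (nrow(spec) == 0) return(train)
  if (any(spec$peak_latency + spec$width >= events$isi)) {
    abort("evoked component extends beyond the inter-stimulus interval.")
  }
  if (is.null(baseline_rate)) {
    span <- diff(range(train$times))
    baseline_rate <- if (length(train$times) >= 2 && span > 0) {
      length(train$times) / span
    } else {
      0
    }
  }
  if (all(spec$gain * baseline_rate == 0)) return(train)

  extra <- with_local_seed(seed, {
    out <- double()
    for (k in seq_len(nrow(spec))) {
      lambda <- spec$gain[k] * baseline_rate * spec$width[k] * sqrt(2 * pi)
      if (lambda <= 0) next
      counts <- rpois(length(events$onsets), lambda)
      total <- sum(counts)
      if (total == 0) next
      offs <- rnorm(total, spec$peak_latency[k], spec$width[k])
      onset_rep <- rep(events$onsets, counts)
      ok <- offs >= 0 & offs < events$isi
      out <- c(out, onset_rep[ok] + offs[ok])
    }
    out
  })
  times <- sort(unique(c(train$times, extra)))
  spike_train(times, region = train$region, unit_kind = train$unit_kind,
              id = train$id)
}

#' Generate a synthetic LFP channel
#'
#' The LFP is a shared delta-band (0.3–2 Hz) Gaussian drive — identical
#' for the two regions except that the TCC copy is delayed by
#' `coupling_lag` via an exact FFT fractional delay — whose amplitude is
#' modulated by the shared slow-rhythm envelope (so the delta power of
#' the LFP waxes and wanes with the slow oscillation of the population
#' rate), scaled by the region's delta-rhythm depth, plus white
#' measurement noise of sd `lfp_noise_sd`. Calling with the same `seed`
#' for both regions yields a coupled pair.
#'
#' @param config a [generator_config()].
#' @param region `"LC"` or `"TCC"`.
#' @param seed RNG seed; use the same value for both regions of a pair.
#' @return an lfp-kind [uniform_signal()] sampled at `config$fs_lfp`.
#' @export
make_lfp <- function(config, region = c("LC", "TCC"), seed = config$seed) {
  region <- match.arg(region)
  stopifnot(inherits(config, "generator_config"))
  fs <- config$fs_lfp
  n <- max(2L, round(config$duration * fs))
  lag <- if (region == "TCC") config$coupling_lag else 0

  white <- with_local_seed(derive_seed(seed, 301), rnorm(n))
  spec <- fft(white)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  keep <- abs(freqs) >= 0.3 & abs(freqs) <= 2
  spec[!keep] <- 0
  if (lag != 0) spec <- spec * exp(-2i * pi * freqs * lag)
  drive <- Re(fft(spec, inverse = TRUE)) / n
  drive_sd <- sqrt(mean(drive^2))
  if (drive_sd > 0) drive <- drive / drive_sd

  # delta amplitude follows the shared slow-rhythm envelope
  slow <- config$rhythms[[region]]$slow
  envelope <- if (!is.null(slow) && slow$depth > 0) {
    t <- (seq_len(n) - 1) / fs
    pmax(1 + slow$depth * cos(2 * pi * (t - lag) / slow$period + slow$phase0), 0)
  } else {
    1
  }

  depth <- config$rhythms[[region]]$delta$depth %||% 0
  noise <- if (config$lfp_noise_sd > 0) {
    with_local_seed(derive_seed(seed, 310 + (region == "TCC")),
                    rnorm(n, 0, config$lfp_noise_sd))
  } else {
    0
  }
  uniform_signal(depth * envelope * drive + noise, fs = fs, t0 = 0,
                 kind = "lfp_raw")
}

# Place electrical trains inside a session, leaving two >= 10 min
# inter-train gaps whenever the duration allows (so that the
# synchronization index is computable).
layout_event_trains <- function(duration, n_stim = 50) {
  cut_len <- function(n) (n - 1) * 1.5
  men_len <- function(n) (n - 1) * 2.0
  trains <- list()
  if (duration >= 2 * 30 + cut_len(n_stim) + 2 * men_len(n_stim) + 2 * 610) {
    gap <- (duration - 60 - cut_len(n_stim) - 2 * men_len(n_stim)) / 2
    t1 <- 30
    t2 <- t1 + cut_len(n_stim) + gap
    t3 <- t2 + men_len(n_stim) + gap
    trains <- list(stim_train(t1, n_stim, "cutaneous"),
                   stim_train(t2, n_stim, "meningeal"),
                   stim_train(t3, n_stim, "meningeal"))
  } else if (duration >= cut_len(n_stim) + men_len(n_stim) + 3 * 10) {
    m <- (duration - cut_len(n_stim) - men_len(n_stim)) / 3
    trains <- list(stim_train(m, n_stim, "cutaneous"),
                   stim_train(m + cut_len(n_stim) + m, n_stim, "meningeal"))
  } else {
    n_fit <- max(2L, floor(0.8 * duration / 2.0) + 1L)
    n_fit <- min(n_fit, n_stim)
    if (men_len(n_fit) + 2 < duration) {
      trains <- list(stim_train(0.1 * duration, n_fit, "meningeal"))
    }
  }
  trains
}

#' Generate a complete synthetic session
#'
#' Composes [rate_process()], [sample_spikes()], [add_evoked()] and
#' [make_lfp()] into a [session()]: an LC multi-unit cluster (the union
#' of `n_subtrains` independently thinned trains), a TCC single unit,
#' electrical stimulation trains laid out to leave two 10-minute
#' inter-train windows when the duration allows, one LFP channel per
#' region, and the config stored as ground truth. Identical configs
#' (including seed) give bit-identical sessions.
#'
#' @param config a [generator_config()].
#' @param events optional list of [event_series()] overriding the
#'   automatic train layout.
#' @param lfp if `FALSE`, skip LFP generation (cheaper for spike-only
#'   analyses).
#' @return a [session()] with `ground_truth = config`.
#' @examples
#' s <- generate_session(preset("naive", seed = 1, duration = 60), lfp = FALSE)
#' s
#' @export
generate_session <- function(config, events = NULL, lfp = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(events)) {
    events <- layout_event_trains(config$duration, config$n_stim)
  }

  lc_rate <- rate_process(config, "LC")
  tcc_rate <- rate_process(config, "TCC")

  # LC MUA: superposition of independently thinned sub-trains, each
  # carrying an equal share of the population rate.
  sub_rate <- uniform_signal(lc_rate$values / config$n_subtrains,
                             fs = lc_rate$fs, t0 = lc_rate$t0, kind = "rate")
  lc_times <- sort(unique(unlist(lapply(seq_len(config$n_subtrains), function(k) {
    sample_spikes(sub_rate, seed = derive_seed(config$seed, 20 + k))$times
  }))))
  lc_mua <- spike_train(lc_times, region = "LC", unit_kind = "MUA", id = "LC_MUA")
  tcc_su <- sample_spikes(tcc_rate, seed = derive_seed(config$seed, 40),
                          region = "TCC", unit_kind = "SU", id = "TCC_SU")

  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$label == "meningeal") {
      lc_mua <- add_evoked(lc_mua, ev, config$evoked$LC,
                           seed = derive_seed(config$seed, 60 + i),
                           baseline_rate = config$base_rate[["LC"]])
    } else if (ev$label == "cutaneous") {
      tcc_su <- add_evoked(tcc_su, ev, config$evoked$TCC,
                           seed = derive_seed(config$seed, 80 + i),
                           baseline_rate = config$base_rate[["TCC"]])
    }
  }

  lfp_list <- list()
  if (isTRUE(lfp)) {
    lfp_list <- list(LC = make_lfp(config, "LC", seed = config$seed),
                     TCC = make_lfp(config, "TCC", seed = config$seed))
  }

  session(duration = config$duration,
          spike_trains = list(lc_mua, tcc_su),
          events = events, lfp = lfp_list,
          condition = config$condition, ground_truth = config)
}
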