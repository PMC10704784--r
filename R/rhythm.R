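# Spontaneous-rhythm analysis: spike-train mean frequency, oscillation
# period estimation, instantaneous phase, spike-phase histograms,
# preferred phase and precession.

#' Frequency band specification
#'
#' The three analysis bands. Delta is 0.3–2 Hz; the slow and
#' intermediate band edges are design choices bracketing the observed
#' rhythm periods (slow ~400–675 s, intermediate ~20–21 s) with margin:
#' slow = \[1/1200, 1/120\] Hz, intermediate = \[1/40, 1/12\] Hz.
#'
#' @param name `"slow"`, `"intermediate"` or `"delta"`, or `"custom"`
#'   with explicit edges.
#' @param low,high band edges in Hz (only for `name = "custom"`).
#' @return list of class `band_spec` with fields `low`, `high`, `name`.
#' @examples
#' band_spec("intermediate")
#' @export
band_spec <- function(name = c("slow", "intermediate", "delta", "custom"),
                      low = NULL, high = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
                  slow = c(1 / 1200, 1 / 120),
                  intermediate = c(1 / 40, 1 / 12),
                  delta = c(0.3, 2),
                  custom = c(low, high))
  if (is.null(edges[1]) || is.null(edges[2])) {
    abort("custom band needs explicit `low` and `high`.")
  }
  if (!(edges[1] > 0 && edges[1] < edges[2])) {
    abort("band edges must satisfy 0 < low < high.")
  }
  structure(list(low = edges[1], high = edges[2], name = name),
            class = "band_spec")
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) band else band_spec(band)
}

#' Mean-frequency estimate of a spike train
#'
#' The instantaneous rate at each spike is the spike count in a centred
#' window of length `width` divided by `width`; these per-spike values
#' are then linearly interpolated onto a uniform grid at `fs_out`.
#' Grid samples farther than `width / 2` from any spike are set to zero.
#' Typical widths: 100 s for slow-rhythm analyses, 10 s for
#' intermediate, 0.5 s for delta-band power.
#'
#' @param train a [spike_train()].
#' @param width centred counting-window length, seconds.
#' @param fs_out output sampling rate, Hz.
#' @param t_start,t_end span of the output grid, seconds; `t_end`
#'   defaults to the last spike time (or `t_start + width` for an empty
#'   train).
#' @return a rate-kind [uniform_signal()].
#' @export
mean_frequency <- function(train, width, fs_out, t_start = 0, t_end = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (width <= 0 || fs_out <= 0) abort("`width` and `fs_out` must be > 0.")
  if (is.null(t_end)) {
    t_end <- if (length(train$times)) max(train$times) else t_start + width
  }
  grid <- seq(t_start, t_end, by = 1 / fs_out)
  if (length(grid) < 2) abort("output grid has fewer than 2 samples.")
  if (length(train$times) == 0) {
    return(uniform_signal(rep(0, length(grid)), fs = fs_out, t0 = t_start,
                          kind = "rate"))
  }
  times <- train$times
  counts <- findInterval(times + width / 2, times) -
    findInterval(times - width / 2, times, left.open = TRUE)
  rate_at_spikes <- counts / width
  vals <- if (length(times) == 1) {
    rep(rate_at_spikes, length(grid))
  } else {
    approx(times, rate_at_spikes, xout = grid, rule = 2)$y
  }
  # zero where no spike lies within width/2 of the grid sample
  nearest <- findInterval(grid, times)
  d_prev <- ifelse(nearest >= 1, grid - times[pmax(nearest, 1)], Inf)
  d_next <- ifelse(nearest < length(times),
                   times[pmin(nearest + 1, length(times))] - grid, Inf)
  vals[pmin(d_prev, d_next) > width / 2] <- 0
  uniform_signal(vals, fs = fs_out, t0 = t_start, kind = "rate")
}

#' Estimate the oscillation period of a rate signal within a band
#'
#' The signal is decimated to a working rate suited to the band,
#' band-passed with a zero-phase FIR filter, and autocorrelated; the
#' period is the lag of the highest positive-lag autocorrelation peak
#' within `[1/high, 1/low]`, refined by parabolic interpolation.
#' Confidence is gated by Fisher's g-test on the in-band periodogram of
#' the unfiltered (decimated) signal — the autocorrelation of a
#' band-filtered signal is periodic even for white-noise input, so the
#' presence of a genuine spectral peak must be established before
#' filtering. Without a significant peak (or without any positive
#' autocorrelation peak in range) the estimate is low-confidence: `NA`
#' is returned with a warning.
#'
#' @param rate a rate-kind [uniform_signal()] spanning at least
#'   `3 / low` seconds (three times the longest in-band period).
#' @param band a [band_spec()] or band name.
#' @return period in seconds (attribute `peak_corr` carries the peak
#'   autocorrelation), or `NA` when low-confidence.
#' @export
estimate_period <- function(rate, band) {
  stopifnot(inherits(rate, "uniform_signal"))
  band <- as_band(band)
  dur <- signal_duration(rate)
  min_dur <- 3 / band$low
  if (dur < min_dur) {
    abort(sprintf("signal spans %.1f s; period estimation in this band needs at least %.1f s.",
                  dur, min_dur))
  }
  # decimate so the band occupies a sensible fraction of the Nyquist range
  q <- max(1L, floor(rate$fs / (12 * band$high)))
  vals <- fir_decimate(rate$values, q)
  fs <- rate$fs / q

  # Fisher's g: is any single in-band periodogram ordinate an outlying
  # fraction of the in-band power?
  centered <- vals - mean(vals)
  pg <- Mod(fft(centered))^2
  pfreq <- (seq_along(pg) - 1) * fs / length(pg)
  in_band_bins <- pfreq >= band$low & pfreq <= band$high & pfreq <= fs / 2
  m <- sum(in_band_bins)
  g_p <- 1
  if (m >= 4 && sum(pg[in_band_bins]) > 0) {
    g <- max(pg[in_band_bins]) / sum(pg[in_band_bins])
    g_p <- min(1, m * (1 - g)^(m - 1))
  }

  filtered <- fir_bandpass_zerophase(vals, fs, band$low, band$high)
  lag_max <- min(length(filtered) - 2L, ceiling(fs / band$low))
  ac <- acf(filtered, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L

  in_range <- lags / fs >= 1 / band$high & lags / fs <= 1 / band$low
  cand <- which(in_range)
  cand <- cand[cand > 1 & cand < length(ac)]
  is_peak <- ac[cand] > ac[cand - 1] & ac[cand] >= ac[cand + 1]
  peaks <- cand[is_peak & ac[cand] > 0]
  if (length(peaks) == 0 || g_p > 0.05) {
    warn("no confident in-band spectral peak: period estimate is low-confidence.")
    return(structure(NA_real_, peak_corr = if (length(peaks)) max(ac[peaks]) else NA_real_))
  }
  k <- peaks[which.max(ac[peaks])]
  # parabolic refinement around the peak
  num <- ac[k - 1] - ac[k + 1]
  den <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
  delta <- if (den != 0) 0.5 * num / den else 0
  structure((lags[k] + delta) / fs, peak_corr = ac[k])
}

#' Instantaneous phase of a rate signal within a band
#'
#' Zero-phase FIR band-pass followed by the analytic-signal (Hilbert)
#' angle, using the cosine convention: phase 0 at the oscillation peak.
#' The first and last filter-length samples are edge-contaminated; their
#' span is recorded in the `valid_from` / `valid_to` attributes and
#' [phase_histogram()] excludes spikes falling outside it.
#'
#' @param rate a rate-kind [uniform_signal()] spanning at least 3 cycles
#'   of `1 / low`.
#' @param band a [band_spec()] or band name.
#' @return a phase-kind [uniform_signal()] with values in (-pi, pi].
#' @export
instantaneous_phase <- function(rate, band) {
  stopifnot(inherits(rate, "uniform_signal"))
  band <- as_band(band)
  if (band$high >= rate$fs / 2) abort("band extends beyond the Nyquist frequency.")
  dur <- signal_duration(rate)
  if (dur < 3 / band$low) {
    abort(sprintf("signal spans %.1f s; phase extraction needs at least %.1f s.",
                  dur, 3 / band$low))
  }
  filtered <- fir_bandpass_zerophase(rate$values, rate$fs, band$low, band$high)
  ph <- wrap_phase(analytic_phase(filtered))
  edge <- min(round(4 * rate$fs / band$low), floor(length(ph) / 3))
  out <- uniform_signal(ph, fs = rate$fs, t0 = rate$t0, kind = "phase")
  attr(out, "valid_from") <- rate$t0 + edge / rate$fs
  attr(out, "valid_to") <- rate$t0 + (length(ph) - 1 - edge) / rate$fs
  out
}

#' Spike-phase histogram
#'
#' Allocates each spike to the phase bin (75 or 150 bins per cycle) of
#' the reference phase signal at the sample nearest the spike time.
#' Counts are z-scored (mean 0, sd 1) so that histograms can be averaged
#' across sessions as pure temporal-dynamics profiles. The preferred
#' phase is the circular mean of the spike phases (robust to bin noise,
#' unlike the argmax bin). Spikes outside the phase signal's valid span
#' are excluded and their number reported in the `n_excluded` attribute.
#'
#' @param train a [spike_train()].
#' @param phase a phase-kind [uniform_signal()] from
#'   [instantaneous_phase()].
#' @param n_bins 75 or 150.
#' @return A tibble of class `phase_histogram` with columns `bin_center`
#'   (radians), `count`, `z`, and attributes `n_bins`, `preferred`,
#'   `n_spikes`, `n_excluded`.
#' @export
phase_histogram <- function(train, phase, n_bins = 150) {
  stopifnot(inherits(train, "spike_train"), inherits(phase, "uniform_signal"))
  if (phase$kind != "phase") abort("`phase` must be a phase-kind signal.")
  if (!n_bins %in% c(75L, 150L)) abort("`n_bins` must be 75 or 150.")
  t_lo <- attr(phase, "valid_from") %||% phase$t0
  t_hi <- attr(phase, "valid_to") %||% (phase$t0 + signal_duration(phase))

  keep <- train$times >= t_lo & train$times <= t_hi
  n_excluded <- sum(!keep)
  times <- train$times[keep]
  idx <- pmin(pmax(round((times - phase$t0) * phase$fs) + 1, 1),
              length(phase$values))
  phases <- phase$values[idx]

  width <- 2 * pi / n_bins
  bins <- pmin(floor((phases + pi) / width), n_bins - 1L) + 1L
  counts <- tabulate(bins, nbins = n_bins)
  z <- if (sd(counts) > 0) (counts - mean(counts)) / sd(counts) else rep(0, n_bins)
  preferred <- if (length(phases)) {
    wrap_phase(Arg(sum(exp(1i * phases))))
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    bin_center = -pi + width * (seq_len(n_bins) - 0.5),
    count = as.integer(counts), z = z
  )
  structure(out, class = c("phase_histogram", class(out)),
            n_bins = as.integer(n_bins), preferred = preferred,
            n_spikes = length(phases), n_excluded = n_excluded)
}

#' Preferred phase of a phase histogram
#' @param x a [phase_histogram()].
#' @return circular-mean preferred phase in radians.
#' @export
preferred_phase <- function(x) {
  stopifnot(inherits(x, "phase_histogram"))
  attr(x, "preferred")
}

#' Phase precession between two regions
#'
#' Circular difference between the two preferred phases
#' (`tcc - lc`, wrapped to (-pi, pi]). Both histograms must have been
#' built against the same reference phase signal with the same number of
#' bins. A positive value means the TCC preferred phase is shifted by
#' that amount on the shared cycle relative to the LC (the generator's
#' `tcc_phase_advance` is recovered with this sign).
#'
#' @param tcc,lc [phase_histogram()] objects for the two regions.
#' @return radians in (-pi, pi].
#' @export
precession <- function(tcc, lc) {
  stopifnot(inherits(tcc, "phase_histogram"), inherits(lc, "phase_histogram"))
  if (attr(tcc, "n_bins") != attr(lc, "n_bins")) {
    abort("phase histograms were built with different bin counts.")
  }
  wrap_phase(attr(tcc, "preferred") - attr(lc, "preferred"))
}

#' @export
autoplot.phase_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$z)) +
    ggplot2::geom_col(width = 2 * pi / attr(object, "n_bins"),
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "preferred"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "phase (rad)", y = "z-scored spike count") +
    ggplot2::theme_minimal()
}
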