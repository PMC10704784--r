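# MUA delta-power synchronization and LFP analyses: band-power ratios,
# the inter-train synchronization index, decimation to 50 Hz, STFT
# spectrograms, the integrated delta-band time course, sliding-window
# R^2 against the slow rate oscillation, and cross-correlogram lag.

#' Delta-band power fraction of a rate signal
#'
#' Periodogram power integrated over the delta band (0.3–2 Hz) divided
#' by the total power above 0 Hz (DC excluded, full Nyquist bandwidth).
#' Always in \[0, 1\] and invariant under amplitude scaling.
#'
#' @param rate a rate-kind [uniform_signal()] with `fs >= 4` Hz.
#' @param window optional `c(from, to)` window in seconds (half-open);
#'   must span at least `10 / 0.3` s so the band is resolved.
#' @return dimensionless ratio in \[0, 1\]; `NA` with a warning for a
#'   constant (zero AC power) signal.
#' @export
delta_power_ratio <- function(rate, window = NULL) {
  stopifnot(inherits(rate, "uniform_signal"))
  if (rate$fs < 4) abort("`rate` must be sampled at >= 4 Hz.")
  x <- if (is.null(window)) rate else signal_window(rate, window[1], window[2])
  if (signal_duration(x) < 10 / 0.3) {
    abort("window shorter than 10/0.3 s: too few delta cycles to resolve the band.")
  }
  v <- x$values - mean(x$values)
  if (all(v == 0)) {
    warn("constant signal: delta power ratio undefined.")
    return(NA_real_)
  }
  n <- length(v)
  p <- Mod(fft(v))^2
  freqs <- (seq_len(n) - 1) * x$fs / n
  pos <- freqs > 0 & freqs <= x$fs / 2
  in_band <- pos & freqs >= 0.3 & freqs <= 2
  sum(p[in_band]) / sum(p[pos])
}

# Inter-train gaps of a session's stimulation trains: intervals from the
# end of one train (last onset + isi) to the start of the next.
inter_train_gaps <- function(stim_trains) {
  if (length(stim_trains) < 2) return(tibble::tibble(from = double(), to = double()))
  starts <- vapply(stim_trains, function(ev) ev$onsets[1], double(1))
  ends <- vapply(stim_trains, function(ev) max(ev$onsets) + ev$isi, double(1))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  tibble::tibble(from = ends[-length(ends)], to = starts[-1])
}

#' MUA delta-synchronization index
#'
#' Mean delta-power ratio over two 10-minute windows lying strictly
#' between electrical stimulation trains (the before/after comparison
#' epochs of the microinjection protocol). Windows are centred in the
#' two longest qualifying gaps.
#'
#' @param rate a rate-kind [uniform_signal()] (mean frequency of the
#'   multi-unit activity, conventionally 0.5 s windows at 50 Hz).
#' @param stim_trains list of [event_series()] stimulation trains.
#' @return A tibble of class `sync_index` with columns `window_start`,
#'   `window_end`, `ratio`, and attribute `value` (the mean ratio,
#'   also returned by `sync_value()`).
#' @export
sync_index <- function(rate, stim_trains) {
  stopifnot(inherits(rate, "uniform_signal"))
  gaps <- inter_train_gaps(stim_trains)
  win <- 600
  gaps <- gaps[gaps$to - gaps$from >= win, , drop = FALSE]
  if (nrow(gaps) < 2) {
    all_gaps <- inter_train_gaps(stim_trains)
    abort(sprintf(
      "need two inter-train gaps of >= 600 s; available gaps (s): %s",
      if (nrow(all_gaps)) paste(sprintf("%.0f", all_gaps$to - all_gaps$from),
                                collapse = ", ") else "none"))
  }
  gaps <- head(gaps[order(gaps$to - gaps$from, decreasing = TRUE), ], 2)
  gaps <- gaps[order(gaps$from), ]
  rows <- lapply(seq_len(nrow(gaps)), function(i) {
    mid <- (gaps$from[i] + gaps$to[i]) / 2
    from <- mid - win / 2
    tibble::tibble(window_start = from, window_end = from + win,
                   ratio = delta_power_ratio(rate, c(from, from + win)))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sync_index", class(out)),
            value = mean(out$ratio))
}

#' Value of a synchronization index
#' @param x a [sync_index()].
#' @return mean delta-power ratio over the two windows.
#' @export
sync_value <- function(x) {
  stopifnot(inherits(x, "sync_index"))
  attr(x, "value")
}

#' Decimate a raw LFP signal to 50 Hz
#'
#' Zero-phase FIR anti-alias low-pass (cutoff 20 Hz, below the 25 Hz
#' output Nyquist) followed by downsampling. Inputs whose rate is an
#' integer multiple of 50 Hz are subsampled directly; other rates are
#' linearly interpolated onto the 50 Hz grid after filtering.
#'
#' @param lfp an lfp-kind [uniform_signal()] with `fs >= 100` Hz.
#' @return an `lfp_decimated` [uniform_signal()] at 50 Hz.
#' @export
decimate_lfp <- function(lfp) {
  stopifnot(inherits(lfp, "uniform_signal"))
  if (lfp$fs < 100) abort("input sampling rate must be >= 100 Hz.")
  fs_out <- 50
  order <- max(60, round(10 * lfp$fs / fs_out))
  b <- signal::fir1(order, 20 / (lfp$fs / 2), type = "low")
  b <- b / sum(b)  # exact unit DC gain
  filtered <- reflect_filtfilt(b, lfp$values)
  q <- lfp$fs / fs_out
  vals <- if (abs(q - round(q)) < 1e-9) {
    filtered[seq(1, length(filtered), by = round(q))]
  } else {
    grid <- seq(lfp$t0, lfp$t0 + signal_duration(lfp), by = 1 / fs_out)
    approx(signal_times(lfp), filtered, xout = grid, rule = 2)$y
  }
  uniform_signal(vals, fs = fs_out, t0 = lfp$t0, kind = "lfp_decimated")
}

#' Short-time Fourier spectrogram of a decimated LFP
#'
#' STFT with a Hamming window of 1024 samples, overlap 1014 (hop 10
#' samples, i.e. 0.2 s frames at 50 Hz) and FFT length 8096; the log
#' power spectral density is stored. Frequency resolution is 50/8096 Hz
#' per bin.
#'
#' @param lfp50 an [uniform_signal()] at 50 Hz with >= 1024 samples.
#' @param window_length,overlap,nfft STFT parameters.
#' @return list of class `lfp_spectrogram` with fields `times` (frame
#'   centres, s), `freqs` (Hz), `log_psd` (freq x time matrix).
#' @export
spectrogram <- function(lfp50, window_length = 1024, overlap = 1014,
                        nfft = 8096) {
  stopifnot(inherits(lfp50, "uniform_signal"))
  if (length(lfp50$values) < window_length) {
    abort(sprintf("signal has %d samples; the STFT window needs %d.",
                  length(lfp50$values), window_length))
  }
  fs <- lfp50$fs
  sg <- signal::specgram(lfp50$values, n = nfft, Fs = fs,
                         window = signal::hamming(window_length),
                         overlap = overlap)
  w <- signal::hamming(window_length)
  psd <- Mod(sg$S)^2 / (fs * sum(w^2))
  psd[psd < .Machine$double.xmin] <- .Machine$double.xmin
  hop <- window_length - overlap
  n_frames <- ncol(psd)
  times <- lfp50$t0 + ((seq_len(n_frames) - 1) * hop + (window_length - 1) / 2) / fs
  structure(list(times = times, freqs = as.numeric(sg$f), log_psd = log(psd),
                 frame_fs = fs / hop),
            class = "lfp_spectrogram")
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram> %d frames x %d frequency bins, t = [%.1f, %.1f] s\n",
              length(x$times), length(x$freqs), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
autoplot.lfp_spectrogram <- function(object, f_max = 5, ...) {
  keep <- object$freqs <= f_max
  df <- tidyr::expand_grid(time = object$times, freq = object$freqs[keep])
  df$log_psd <- as.vector(t(object$log_psd[keep, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$log_psd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log PSD") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Delta-band time course from a spectrogram
#'
#' Trapezoidal integral of the log-PSD over frequency bins in
#' \[0.3, 2\] Hz, per time frame — a time-varying index of low-frequency
#' LFP activity sampled at the spectrogram frame rate.
#'
#' @param spec an [spectrogram()] result.
#' @param linear integrate the linear PSD instead of its log (sensitivity
#'   switch; the log integral is the default definition).
#' @return a band_power-kind [uniform_signal()] at the frame rate.
#' @export
delta_band_timecourse <- function(spec, linear = FALSE) {
  stopifnot(inherits(spec, "lfp_spectrogram"))
  keep <- spec$freqs >= 0.3 & spec$freqs <= 2
  f <- spec$freqs[keep]
  m <- spec$log_psd[keep, , drop = FALSE]
  if (linear) m <- exp(m)
  df <- diff(f)
  vals <- vapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    sum(df * (y[-1] + y[-length(y)]) / 2)
  }, double(1))
  uniform_signal(vals, fs = spec$frame_fs, t0 = spec$times[1],
                 kind = "band_power")
}

#' Sliding-window R^2 between LFP delta power and the slow rate
#'
#' Both signals are smoothed with a Savitzky-Golay filter (polynomial
#' order 3, frame 51 samples) after interpolating the slow rate onto the
#' band-power grid, and the squared Pearson correlation is computed on
#' 400 s sliding windows (hop 10 s). `r2max` is the maximum over
#' windows. The statistic is invariant to affine transforms of either
#' input.
#'
#' @param band_power a band_power-kind [uniform_signal()] (from
#'   [delta_band_timecourse()]).
#' @param slow_rate a rate-kind [uniform_signal()] (slow mean-frequency
#'   oscillation of the MUA).
#' @param window_s sliding-window length, seconds.
#' @param hop_s window hop, seconds.
#' @param sg_order,sg_frame Savitzky-Golay smoothing parameters.
#' @return list with `r2_series` (a [uniform_signal()] of per-window
#'   R^2 at window centres) and `r2max`.
#' @export
sliding_r2 <- function(band_power, slow_rate, window_s = 400, hop_s = 10,
                       sg_order = 3, sg_frame = 51) {
  stopifnot(inherits(band_power, "uniform_signal"),
            inherits(slow_rate, "uniform_signal"))
  t_lo <- max(band_power$t0, slow_rate$t0)
  t_hi <- min(band_power$t0 + signal_duration(band_power),
              slow_rate$t0 + signal_duration(slow_rate))
  if (t_hi - t_lo < window_s) {
    abort(sprintf("common coverage is %.0f s; sliding R^2 needs >= %.0f s.",
                  t_hi - t_lo, window_s))
  }
  fs <- band_power$fs
  grid <- seq(t_lo, t_hi, by = 1 / fs)
  x <- approx(signal_times(band_power), band_power$values, xout = grid, rule = 2)$y
  y <- approx(signal_times(slow_rate), slow_rate$values, xout = grid, rule = 2)$y
  frame <- min(sg_frame, length(grid) - (1 - length(grid) %% 2))
  if (frame %% 2 == 0) frame <- frame - 1
  x <- signal::sgolayfilt(x, p = sg_order, n = frame)
  y <- signal::sgolayfilt(y, p = sg_order, n = frame)

  win_n <- round(window_s * fs)
  hop_n <- max(1L, round(hop_s * fs))
  starts <- seq(1L, length(grid) - win_n + 1L, by = hop_n)
  r2 <- vapply(starts, function(s) {
    xs <- x[s:(s + win_n - 1L)]
    ys <- y[s:(s + win_n - 1L)]
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)^2
  }, double(1))
  centers <- grid[starts] + window_s / 2
  series <- if (length(r2) >= 2) {
    uniform_signal(r2, fs = fs / hop_n, t0 = centers[1], kind = "band_power")
  } else {
    NULL
  }
  list(r2_series = series, r2max = max(r2, na.rm = TRUE))
}

#' Lag between two LFP signals from the cross-correlogram peak
#'
#' Normalized cross-correlation over lags within `± max_lag`; the
#' returned lag is that of the global peak, refined to sub-sample
#' resolution by a local quadratic fit (disable with
#' `interpolate = FALSE` for integer-sample lags). The fit neighbourhood
#' adapts to the peak's sharpness — the contiguous region above 90% of
#' the peak, capped at 30 ms — so a narrow broadband peak resolves to
#' its sample while the smooth peak of band-limited signals is averaged
#' over its quadratic regime. Sign convention: a positive lag means the
#' first signal (LC) leads the second (TCC). Swapping the inputs flips
#' the sign exactly.
#'
#' @param lfp_lc,lfp_tcc [uniform_signal()]s with equal `fs` and `t0`.
#' @param max_lag maximum |lag| scanned, seconds.
#' @param interpolate parabolically refine the peak to sub-sample
#'   resolution.
#' @return lag in seconds (attribute `peak_corr` carries the peak
#'   correlation); `NA` with a warning for constant inputs.
#' @export
crosscorrelogram_lag <- function(lfp_lc, lfp_tcc, max_lag = 0.2,
                                 interpolate = TRUE) {
  stopifnot(inherits(lfp_lc, "uniform_signal"), inherits(lfp_tcc, "uniform_signal"))
  if (abs(lfp_lc$fs - lfp_tcc$fs) > 1e-9 || abs(lfp_lc$t0 - lfp_tcc$t0) > 1e-9) {
    abort("the two LFP signals must share sampling rate and start time.")
  }
  if (sd(lfp_lc$values) == 0 || sd(lfp_tcc$values) == 0) {
    warn("constant LFP signal: lag undefined.")
    return(NA_real_)
  }
  fs <- lfp_lc$fs
  lag_n <- ceiling(max_lag * fs)
  n <- min(length(lfp_lc$values), length(lfp_tcc$values))
  cc <- stats::ccf(lfp_lc$values[seq_len(n)], lfp_tcc$values[seq_len(n)],
                   lag.max = lag_n, plot = FALSE, demean = TRUE)
  # ccf lag k correlates lc[t+k] with tcc[t]; a positive LC-leads lag d
  # (tcc delayed copy of lc) peaks at k = -d, so flip the axis.
  lags <- -as.numeric(cc$lag) / fs
  vals <- as.numeric(cc$acf)
  ord <- order(lags)
  lags <- lags[ord]; vals <- vals[ord]
  k <- which.max(vals)
  lag_est <- lags[k]
  if (interpolate && k > 1 && k < length(vals)) {
    thr <- 0.9 * vals[k]
    lo <- k; while (lo > 1 && vals[lo - 1] >= thr) lo <- lo - 1
    hi <- k; while (hi < length(vals) && vals[hi + 1] >= thr) hi <- hi + 1
    half_n <- max(1L, min(k - lo, hi - k, as.integer(round(0.03 * fs))))
    sel <- max(1L, k - half_n):min(length(vals), k + half_n)
    if (length(sel) >= 3) {
      u <- lags[sel] - lags[k]
      co <- stats::lm.fit(cbind(1, u, u^2), vals[sel])$coefficients
      if (is.finite(co[3]) && co[3] < 0) {
        vertex <- -co[2] / (2 * co[3])
        if (abs(vertex) <= half_n / fs) lag_est <- lags[k] + vertex
      }
    }
  }
  structure(lag_est, peak_corr = vals[k])
}
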