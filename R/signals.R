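#' Regularly sampled signal
#'
#' The container used throughout the package for anything sampled on a
#' uniform grid: raw and decimated LFP, mean-frequency rate estimates,
#' instantaneous phase, and band-power time courses. Sample `k` (0-based)
#' sits at time `t0 + k / fs`.
#'
#' @param values numeric vector, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds from session start.
#' @param kind one of `"lfp_raw"`, `"lfp_decimated"`, `"rate"`, `"phase"`,
#'   `"band_power"`. Phase-kind values must lie in (-pi, pi].
#' @return An object of class `uniform_signal`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100, kind = "rate")
#' signal_duration(s)
#' @export
uniform_signal <- function(values, fs, t0 = 0,
                           kind = c("rate", "lfp_raw", "lfp_decimated",
                                    "phase", "band_power")) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector of length >= 2.")
  }
  stopifnot_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be > 0.")
  stopifnot_scalar_number(t0, "t0")
  if (kind == "phase") {
    bad <- values <= -pi - 1e-12 | values > pi + 1e-12
    if (any(bad, na.rm = TRUE)) {
      abort("phase-kind values must be wrapped to (-pi, pi].")
    }
  }
  structure(
    list(values = as.double(values), fs = as.double(fs),
         t0 = as.double(t0), kind = kind),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal[%s]> %d samples @ %g Hz, t = [%g, %g] s\n",
              x$kind, length(x$values), x$fs, x$t0,
              x$t0 + (length(x$values) - 1) / x$fs))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample timestamps of a uniform signal
#' @param x a [uniform_signal()].
#' @return numeric vector of times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration spanned by a uniform signal (first to last sample)
#' @param x a [uniform_signal()].
#' @return seconds.
#' @export
signal_duration <- function(x) (length(x$values) - 1) / x$fs

#' @export
as_tibble.uniform_signal <- function(x, ...) {
  tibble::tibble(time = signal_times(x), value = x$values)
}

#' Extract a time window from a uniform signal
#'
#' Windows are half-open `[from, to)`, the package-wide interval
#' convention.
#'
#' @param x a [uniform_signal()].
#' @param from,to window bounds in seconds.
#' @return a [uniform_signal()] restricted to the window.
#' @export
signal_window <- function(x, from, to) {
  stopifnot(inherits(x, "uniform_signal"))
  if (to <= from) abort("`to` must be greater than `from`.")
  times <- signal_times(x)
  keep <- times >= from - 1e-12 & times < to - 1e-12
  if (sum(keep) < 2L) abort("window contains fewer than 2 samples.")
  uniform_signal(x$values[keep], x$fs, t0 = times[which(keep)[1]], kind = x$kind)
}

# Linear interpolation of a signal at arbitrary times; values outside the
# span take the nearest sample (rule = 2).
signal_at <- function(x, t) {
  approx(signal_times(x), x$values, xout = t, rule = 2)$y
}

#' @export
autoplot.uniform_signal <- function(object, ...) {
  df <- as_tibble.uniform_signal(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = switch(object$kind,
                             rate = "rate (Hz)",
                             phase = "phase (rad)",
                             band_power = "band power (a.u.)",
                             "LFP (a.u.)")) +
    ggplot2::theme_minimal()
}
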