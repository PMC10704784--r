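# Internal zero-phase filtering helpers built on the `signal` package.
# All analysis filters are applied forward-backward (filtfilt) so that
# phase and lag estimates carry no group delay. Signals are reflected at
# both ends before filtering (and trimmed after) to suppress the edge
# transients filtfilt would otherwise produce.

reflect_filtfilt <- function(b, x) {
  n <- length(x)
  pad <- min(3 * length(b), n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(b, xp)
  y[(pad + 1):(pad + n)]
}

# Zero-phase FIR band-pass. Order is chosen from the lower band edge
# (more taps for narrower/lower bands) and capped so filtfilt remains
# well conditioned on short signals.
fir_bandpass_zerophase <- function(values, fs, low, high) {
  nyq <- fs / 2
  if (high >= nyq) abort("band upper edge must be below the Nyquist frequency.")
  n <- length(values)
  order <- round(4 * fs / low)
  order <- min(order, floor((n - 1) / 3))
  order <- max(order, 16)
  if (order %% 2 == 1) order <- order + 1
  b <- signal::fir1(order, c(low, high) / nyq, type = "pass")
  reflect_filtfilt(b, values)
}

# Zero-phase FIR low-pass followed by integer-factor subsampling.
fir_decimate <- function(values, q, rel_cutoff = 0.8) {
  if (q <= 1) return(values)
  order <- max(30, 10 * q)
  b <- signal::fir1(order, rel_cutoff / q, type = "low")
  b <- b / sum(b)  # exact unit DC gain
  filtered <- reflect_filtfilt(b, values)
  filtered[seq(1, length(filtered), by = q)]
}

# Analytic-signal phase via the frequency-domain Hilbert transform.
analytic_phase <- function(values) {
  n <- length(values)
  spec <- fft(values)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(spec * h, inverse = TRUE) / n
  Arg(analytic)
}
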