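#' Spike train of one unit or multi-unit cluster
#'
#' Ordered event times of a single unit (SU) or a multi-unit cluster
#' (MUA), tagged with the region it was recorded from. The recording
#' convention of the pipeline is single-unit activity for the
#' trigeminocervical complex (TCC) and multi-unit activity for the locus
#' coeruleus (LC); both are representable and every analysis accepts
#' either.
#'
#' @param times spike times in seconds from session start, strictly
#'   increasing, non-negative.
#' @param region `"LC"` or `"TCC"` (the alias `"Sp5C"` is accepted and
#'   canonicalised to `"TCC"`).
#' @param unit_kind `"SU"` or `"MUA"`.
#' @param id identifier string.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(0.1, 0.5, 1.2), region = "TCC", unit_kind = "SU")
#' @export
spike_train <- function(times, region = c("LC", "TCC", "Sp5C"),
                        unit_kind = c("SU", "MUA"), id = "unit") {
  region <- match.arg(region)
  if (region == "Sp5C") region <- "TCC"
  unit_kind <- match.arg(unit_kind)
  times <- as.double(times)
  if (anyNA(times)) abort(sprintf("spike train '%s': times contain NA.", id))
  if (length(times) > 0) {
    if (any(times < 0)) {
      abort(sprintf("spike train '%s': negative spike times.", id))
    }
    if (length(times) > 1 && any(diff(times) <= 0)) {
      abort(sprintf("spike train '%s': times are not strictly increasing.", id))
    }
  }
  structure(
    list(times = times, region = region, unit_kind = unit_kind,
         id = as.character(id)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> '%s' %s/%s, %d spikes%s\n",
              x$id, x$region, x$unit_kind, length(x$times),
              if (length(x$times)) sprintf(", t = [%g, %g] s",
                                           min(x$times), max(x$times)) else ""))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' @export
as_tibble.spike_train <- function(x, ...) {
  tibble::tibble(time = x$times, region = x$region,
                 unit_kind = x$unit_kind, id = x$id)
}

#' Stimulus event series
#'
#' Onset times of a stimulation protocol. For electrical trains the onset
#' differences must equal the inter-stimulus interval `isi` to within
#' 1e-9 s. The two default pulse protocols are the cutaneous one
#' (0.8 ms pulses every 1.5 s) and the meningeal one (5 ms pulses every
#' 2 s).
#'
#' @param onsets onset times in seconds, strictly increasing.
#' @param pulse_width pulse width in seconds.
#' @param isi inter-stimulus interval in seconds.
#' @param label one of `"cutaneous"`, `"meningeal"`, `"IS_infusion"`,
#'   `"microinjection"`.
#' @param regular if `TRUE` (the default for electrical labels), enforce
#'   that successive onsets differ by exactly `isi` (tolerance 1e-9 s).
#' @return An object of class `event_series`.
#' @examples
#' ev <- event_series(seq(0, by = 1.5, length.out = 50),
#'                    pulse_width = 8e-4, isi = 1.5, label = "cutaneous")
#' n_events(ev)
#' @export
event_series <- function(onsets, pulse_width, isi,
                         label = c("cutaneous", "meningeal", "IS_infusion",
                                   "microinjection"),
                         regular = label %in% c("cutaneous", "meningeal")) {
  label <- match.arg(label)
  onsets <- as.double(onsets)
  if (length(onsets) == 0) abort("event series needs at least one onset.")
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    abort(sprintf("event series '%s': onsets are not strictly increasing.", label))
  }
  stopifnot_scalar_number(pulse_width, "pulse_width")
  stopifnot_scalar_number(isi, "isi")
  if (pulse_width <= 0 || isi <= 0) abort("pulse_width and isi must be > 0.")
  if (isTRUE(regular) && length(onsets) > 1) {
    if (max(abs(diff(onsets) - isi)) > 1e-9) {
      abort(sprintf(
        "event series '%s': electrical-train onsets must be spaced by isi = %g s (tolerance 1e-9 s).",
        label, isi))
    }
  }
  structure(
    list(onsets = onsets, pulse_width = pulse_width, isi = isi, label = label),
    class = "event_series"
  )
}

#' Number of events in an event series
#' @param x an [event_series()].
#' @return integer count.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_series"))
  length(x$onsets)
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> '%s', %d onsets, pulse %g ms every %g s\n",
              x$label, length(x$onsets), 1e3 * x$pulse_width, x$isi))
  invisible(x)
}

#' @export
as_tibble.event_series <- function(x, ...) {
  tibble::tibble(onset = x$onsets, pulse_width = x$pulse_width,
                 isi = x$isi, label = x$label)
}

#' Default electrical stimulation protocols
#'
#' The two pulse protocols used for evoked responses: `"cutaneous"`
#' (0.8 ms pulses delivered every 1.5 s, the classical TCC protocol) and
#' `"meningeal"` (5 ms pulses every 2 s, better suited to evoke LC
#' responses).
#'
#' @param label `"cutaneous"` or `"meningeal"`.
#' @return list with elements `pulse_width` and `isi`, seconds.
#' @export
stim_protocol <- function(label = c("cutaneous", "meningeal")) {
  label <- match.arg(label)
  switch(label,
         cutaneous = list(pulse_width = 0.0008, isi = 1.5),
         meningeal = list(pulse_width = 0.005, isi = 2.0))
}

#' Build a regular electrical stimulation train
#'
#' @param start time of the first pulse, seconds.
#' @param n_stim number of pulses.
#' @param label protocol label, see [stim_protocol()].
#' @return an [event_series()].
#' @examples
#' stim_train(start = 10, n_stim = 50, label = "meningeal")
#' @export
stim_train <- function(start, n_stim = 50, label = c("cutaneous", "meningeal")) {
  label <- match.arg(label)
  p <- stim_protocol(label)
  event_series(start + p$isi * (seq_len(n_stim) - 1),
               pulse_width = p$pulse_width, isi = p$isi, label = label)
}
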