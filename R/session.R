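#' Recording session container
#'
#' Bundles everything recorded (or simulated) in one sitting: spike
#' trains from both regions, stimulation event series, one LFP channel
#' per region, the experimental condition, and — for synthetic sessions
#' only — the generator configuration as ground truth.
#'
#' @param duration session duration in seconds.
#' @param spike_trains list of [spike_train()] objects.
#' @param events list of [event_series()] objects.
#' @param lfp named list of [uniform_signal()] (names `"LC"`/`"TCC"`), or
#'   empty list when no LFP was recorded.
#' @param condition one of `"naive"`, `"sensitized"`, `"propranolol"`,
#'   `"acsf_control"`.
#' @param ground_truth a [generator_config()] for synthetic sessions,
#'   `NULL` otherwise.
#' @return An object of class `session`.
#' @export
session <- function(duration, spike_trains = list(), events = list(),
                    lfp = list(),
                    condition = c("naive", "sensitized", "propranolol",
                                  "acsf_control"),
                    ground_truth = NULL) {
  condition <- match.arg(condition)
  stopifnot_scalar_number(duration, "duration")
  if (duration <= 0) abort("`duration` must be > 0.")
  for (tr in spike_trains) {
    if (!inherits(tr, "spike_train")) abort("`spike_trains` must contain spike_train objects.")
    if (length(tr$times) && max(tr$times) > duration + 1e-9) {
      abort(sprintf("spike train '%s': spike times exceed session duration.", tr$id))
    }
  }
  for (ev in events) {
    if (!inherits(ev, "event_series")) abort("`events` must contain event_series objects.")
  }
  if (length(lfp)) {
    if (is.null(names(lfp)) || !all(names(lfp) %in% c("LC", "TCC"))) {
      abort("`lfp` must be a named list with names in {LC, TCC}.")
    }
    if (anyDuplicated(names(lfp))) abort("exactly one LFP channel per region.")
    for (s in lfp) {
      if (!inherits(s, "uniform_signal")) abort("`lfp` must contain uniform_signal objects.")
    }
  }
  names(spike_trains) <- vapply(spike_trains, function(tr) tr$id, character(1))
  if (anyDuplicated(names(spike_trains))) abort("spike train ids must be unique.")
  names(events) <- make.unique(vapply(events, function(ev) ev$label, character(1)))
  structure(
    list(duration = as.double(duration), spike_trains = spike_trains,
         events = events, lfp = lfp, condition = condition,
         ground_truth = ground_truth),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %g s, condition '%s'%s\n", x$duration, x$condition,
              if (!is.null(x$ground_truth)) " (synthetic)" else ""))
  cat(sprintf("  %d spike trains, %d event series, LFP: %s\n",
              length(x$spike_trains), length(x$events),
              if (length(x$lfp)) paste(names(x$lfp), collapse = ", ") else "none"))
  invisible(x)
}

#' Spike trains of one region
#'
#' @param session a [session()].
#' @param region `"LC"` or `"TCC"`.
#' @param unit_kind optional filter, `"SU"` or `"MUA"`.
#' @return list of [spike_train()].
#' @export
session_trains <- function(session, region, unit_kind = NULL) {
  stopifnot(inherits(session, "session"))
  keep <- vapply(session$spike_trains, function(tr) {
    tr$region == region && (is.null(unit_kind) || tr$unit_kind == unit_kind)
  }, logical(1))
  session$spike_trains[keep]
}

fmt_times <- function(x) sprintf("%.17g", x)

#' Write a session to a directory of CSV files plus JSON metadata
#'
#' Layout: `meta.json` (duration, condition, train/event/LFP descriptors,
#' ground truth when synthetic), `spikes/<id>.csv` (column `time`),
#' `events/<label>.csv` (column `onset`), `lfp/<region>.csv` (column
#' `value`). Times are written with 17 significant digits so the
#' round trip is lossless at double precision.
#'
#' @param session a [session()].
#' @param path directory to create (must not be an existing non-session file).
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create session directory '%s'.", path))
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  dir.create(file.path(path, "events"), showWarnings = FALSE)
  dir.create(file.path(path, "lfp"), showWarnings = FALSE)

  meta <- list(
    format = "duosync-session",
    version = 1L,
    duration = session$duration,
    condition = session$condition,
    spike_trains = lapply(unname(session$spike_trains), function(tr) {
      list(id = tr$id, region = tr$region, unit_kind = tr$unit_kind,
           file = paste0("spikes/", tr$id, ".csv"))
    }),
    events = lapply(seq_along(session$events), function(i) {
      ev <- session$events[[i]]
      list(name = names(session$events)[i], label = ev$label,
           pulse_width = ev$pulse_width, isi = ev$isi,
           file = paste0("events/", names(session$events)[i], ".csv"))
    }),
    lfp = lapply(names(session$lfp), function(rg) {
      s <- session$lfp[[rg]]
      list(region = rg, fs = s$fs, t0 = s$t0, kind = s$kind,
           file = paste0("lfp/", rg, ".csv"))
    }),
    ground_truth = if (!is.null(session$ground_truth)) {
      config_to_list(session$ground_truth)
    }
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  for (tr in session$spike_trains) {
    writeLines(c("time", fmt_times(tr$times)),
               file.path(path, "spikes", paste0(tr$id, ".csv")))
  }
  for (i in seq_along(session$events)) {
    writeLines(c("onset", fmt_times(session$events[[i]]$onsets)),
               file.path(path, "events", paste0(names(session$events)[i], ".csv")))
  }
  for (rg in names(session$lfp)) {
    writeLines(c("value", fmt_times(session$lfp[[rg]]$values)),
               file.path(path, "lfp", paste0(rg, ".csv")))
  }
  invisible(path)
}

read_time_column <- function(file, column) {
  df <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  if (!column %in% names(df)) {
    abort(sprintf("format error: '%s' lacks required column '%s'.", file, column))
  }
  df[[column]]
}

#' Read a session written by [write_session()]
#'
#' All container invariants (strictly increasing times, spikes within the
#' session span, regular electrical trains, one LFP per region) are
#' re-validated on read; violations raise errors naming the offending
#' record.
#'
#' @param path session directory.
#' @return a [session()].
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    abort(sprintf("format error: '%s' is not a session directory (no meta.json).", path))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  for (field in c("duration", "condition", "spike_trains", "events", "lfp")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("format error: meta.json lacks required field '%s'.", field))
    }
  }
  trains <- lapply(meta$spike_trains, function(m) {
    spike_train(read_time_column(file.path(path, m$file), "time"),
                region = m$region, unit_kind = m$unit_kind, id = m$id)
  })
  events <- lapply(meta$events, function(m) {
    event_series(read_time_column(file.path(path, m$file), "onset"),
                 pulse_width = m$pulse_width, isi = m$isi, label = m$label)
  })
  lfp <- list()
  for (m in meta$lfp) {
    lfp[[m$region]] <- uniform_signal(read_time_column(file.path(path, m$file), "value"),
                                      fs = m$fs, t0 = m$t0, kind = m$kind)
  }
  gt <- if (!is.null(meta$ground_truth)) config_from_list(meta$ground_truth)
  session(duration = meta$duration, spike_trains = trains, events = events,
          lfp = lfp, condition = meta$condition, ground_truth = gt)
}
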