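# Orchestration: run every feasible analysis on a session and collect a
# coupling report; compare report fields across conditions with the
# normality-gated tests.

#' Analysis settings for [run_coupling_analysis()]
#'
#' Defaults: mean-frequency widths of 100 s / 10 s / 0.5 s for the
#' slow / intermediate / delta analyses, output rates of 2 Hz
#' (slow, intermediate) and 50 Hz (delta), 1 ms PSTH bins over one
#' inter-stimulus interval, 150 phase bins, 0.2 s maximum LFP lag.
#'
#' @param slow_width,int_width,delta_width mean-frequency window widths
#'   (s).
#' @param rate_fs,delta_fs output rates (Hz) of the slow/intermediate and
#'   delta mean-frequency signals.
#' @param psth_bin PSTH bin width (s).
#' @param n_phase_bins 75 or 150.
#' @param phase_band band used for the spike-phase / precession analysis;
#'   `"auto"` picks the slow band when the session is long enough
#'   (>= 3 of its longest periods) and falls back to the intermediate
#'   band.
#' @param max_lag maximum |lag| scanned on the LFP cross-correlogram (s).
#' @return named list of settings.
#' @export
analysis_settings <- function(slow_width = 100, int_width = 10,
                              delta_width = 0.5, rate_fs = 2, delta_fs = 50,
                              psth_bin = 0.001, n_phase_bins = 150,
                              phase_band = "auto", max_lag = 0.2) {
  list(slow_width = slow_width, int_width = int_width,
       delta_width = delta_width, rate_fs = rate_fs, delta_fs = delta_fs,
       psth_bin = psth_bin, n_phase_bins = n_phase_bins,
       phase_band = phase_band, max_lag = max_lag)
}

#' Run the full coupling analysis on one session
#'
#' Composes the evoked, rhythm and synchronization analyses into a
#' [coupling_report()]. Stages that are infeasible for the session
#' (no LFP, too short for a band, no qualifying inter-train gaps, ...)
#' are skipped and the reason recorded; everything computed is
#' deterministic given the session and settings.
#'
#' @param session a [session()].
#' @param settings an [analysis_settings()] list.
#' @return a [coupling_report()].
#' @export
run_coupling_analysis <- function(session, settings = analysis_settings()) {
  stopifnot(inherits(session, "session"))
  reasons <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      reasons[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  dur <- session$duration

  lc_list <- session_trains(session, "LC")
  tcc_list <- session_trains(session, "TCC")
  lc <- if (length(lc_list)) lc_list[[1]] else NULL
  tcc <- if (length(tcc_list)) tcc_list[[1]] else NULL

  men <- Filter(function(ev) ev$label == "meningeal", session$events)
  cut <- Filter(function(ev) ev$label == "cutaneous", session$events)

  # --- evoked components ------------------------------------------------
  evoked <- NULL
  lc_early_mag <- NA_real_
  a_total <- NA_real_
  if (!is.null(lc) && length(men)) {
    comp <- try_stage("lc_evoked", {
      p <- build_psth(lc, men[[1]], bin_width = settings$psth_bin)
      extract_components(p, region = "LC")
    })
    if (!is.null(comp) && nrow(comp)) {
      comp$region <- "LC"
      evoked <- dplyr::bind_rows(evoked, comp)
      if (any(comp$kind == "early")) {
        lc_early_mag <- comp$magnitude[comp$kind == "early"][1]
      }
    }
  } else if (is.null(lc)) {
    reasons$lc_evoked <- "no LC spike train"
  } else {
    reasons$lc_evoked <- "no meningeal stimulation train"
  }
  if (!is.null(tcc) && length(cut)) {
    comp <- try_stage("tcc_evoked", {
      p <- build_psth(tcc, cut[[1]], bin_width = settings$psth_bin)
      extract_components(p, region = "TCC")
    })
    if (!is.null(comp) && nrow(comp)) {
      comp$region <- "TCC"
      evoked <- dplyr::bind_rows(evoked, comp)
    }
    counts <- try_stage("tcc_counts", tcc_train_counts(tcc, cut[[1]]))
    if (!is.null(counts)) a_total <- counts$A_total
  } else {
    reasons$tcc_evoked <- if (is.null(tcc)) "no TCC spike train" else "no cutaneous stimulation train"
  }
  lc_tcc <- if (!is.na(lc_early_mag) && !is.na(a_total) && a_total > 0) {
    lc_tcc_evoked_ratio(list(magnitude = lc_early_mag), a_total)
  } else {
    reasons$lc_tcc_ratio <- "needs an LC early component and a nonzero TCC A response"
    NULL
  }

  # --- oscillation periods ---------------------------------------------
  periods <- NULL
  rates <- list()
  for (rg in c("LC", "TCC")) {
    tr <- if (rg == "LC") lc else tcc
    if (is.null(tr)) next
    for (bn in c("slow", "intermediate")) {
      band <- band_spec(bn)
      if (dur < 3 / band$low) {
        reasons[[paste0(rg, "_", bn, "_period")]] <-
          sprintf("session shorter than 3 x %.0f s", 1 / band$low)
        next
      }
      width <- if (bn == "slow") settings$slow_width else settings$int_width
      key <- paste0(rg, "_", bn)
      rates[[key]] <- mean_frequency(tr, width = width, fs_out = settings$rate_fs,
                                     t_end = dur)
      p <- try_stage(paste0(key, "_period"),
                     suppressWarnings(estimate_period(rates[[key]], band)))
      if (!is.null(p) && !is.na(p)) {
        periods <- dplyr::bind_rows(periods,
                                    tibble::tibble(region = rg, rhythm = bn,
                                                   period = as.numeric(p)))
      }
    }
  }

  # --- spike-phase preference and precession ---------------------------
  preferred <- NULL
  prec <- NULL
  phase_bn <- settings$phase_band
  if (identical(phase_bn, "auto")) {
    phase_bn <- if (dur >= 3 / band_spec("slow")$low) "slow" else "intermediate"
  }
  if (!is.null(lc) && !is.null(tcc) && dur >= 3 / band_spec(phase_bn)$low) {
    ph <- try_stage("phase", {
      ref_rate <- rates[[paste0("LC_", phase_bn)]]
      if (is.null(ref_rate)) {
        width <- if (phase_bn == "slow") settings$slow_width else settings$int_width
        ref_rate <- mean_frequency(lc, width = width, fs_out = settings$rate_fs,
                                   t_end = dur)
      }
      instantaneous_phase(ref_rate, phase_bn)
    })
    if (!is.null(ph)) {
      h_lc <- phase_histogram(lc, ph, settings$n_phase_bins)
      h_tcc <- phase_histogram(tcc, ph, settings$n_phase_bins)
      preferred <- tibble::tibble(
        region = c("LC", "TCC"), rhythm = phase_bn,
        phase = c(preferred_phase(h_lc), preferred_phase(h_tcc))
      )
      prec <- precession(h_tcc, h_lc)
    }
  } else {
    reasons$phase <- "needs both regions and >= 3 cycles of the phase band"
  }

  # --- MUA delta synchronization ---------------------------------------
  delta_ratio <- NULL
  for (rg in c("LC", "TCC")) {
    tr <- if (rg == "LC") lc else tcc
    if (is.null(tr)) next
    val <- try_stage(paste0(rg, "_delta_ratio"), {
      dr <- mean_frequency(tr, width = settings$delta_width,
                           fs_out = settings$delta_fs, t_end = dur)
      si <- tryCatch(sync_value(sync_index(dr, unname(session$events))),
                     error = function(e) NULL)
      if (is.null(si)) suppressWarnings(delta_power_ratio(dr)) else si
    })
    if (!is.null(val) && !is.na(val)) {
      delta_ratio <- dplyr::bind_rows(delta_ratio,
                                      tibble::tibble(region = rg, ratio = val))
    }
  }

  # --- LFP: delta power vs slow rate, and lag ---------------------------
  r2max <- NULL
  lfp_lag <- NULL
  if (all(c("LC", "TCC") %in% names(session$lfp))) {
    lfp_lag <- try_stage("lfp_lag", {
      as.numeric(crosscorrelogram_lag(session$lfp$LC, session$lfp$TCC,
                                      max_lag = settings$max_lag))
    })
    r2max <- try_stage("r2max", {
      dec <- decimate_lfp(session$lfp$LC)
      tc <- delta_band_timecourse(spectrogram(dec))
      slow <- rates[["LC_slow"]]
      if (is.null(slow)) {
        slow <- mean_frequency(lc, width = settings$slow_width,
                               fs_out = settings$rate_fs, t_end = dur)
      }
      sliding_r2(tc, slow)$r2max
    })
  } else {
    reasons$lfp <- "no LFP"
    reasons$r2max <- "no LFP"
    reasons$lfp_lag <- "no LFP"
  }

  coupling_report(
    evoked = evoked, periods = periods, preferred = preferred,
    precession = if (!is.null(prec)) as.numeric(prec),
    delta_ratio = delta_ratio,
    r2max = if (!is.null(r2max)) min(max(r2max, 0), 1),
    lfp_lag = lfp_lag, lc_tcc_ratio = lc_tcc,
    condition = session$condition, reasons = reasons
  )
}

# Scalar accessor for contrastable report fields.
report_field <- function(report, field) {
  g <- glance(report)
  extra <- list(
    lc_early_magnitude = function(r) {
      if (is.null(r$evoked)) return(NA_real_)
      v <- r$evoked$magnitude[r$evoked$region == "LC" & r$evoked$kind == "early"]
      if (length(v)) v[1] else NA_real_
    },
    lc_late_magnitude = function(r) {
      if (is.null(r$evoked)) return(NA_real_)
      v <- r$evoked$magnitude[r$evoked$region == "LC" & r$evoked$kind == "late"]
      if (length(v)) v[1] else NA_real_
    },
    tcc_c_spikes = function(r) {
      if (is.null(r$evoked)) return(NA_real_)
      v <- r$evoked$total_spikes[r$evoked$region == "TCC" & r$evoked$kind == "C"]
      if (length(v)) as.numeric(v[1]) else NA_real_
    }
  )
  if (field %in% names(g)) {
    as.numeric(g[[field]])
  } else if (field %in% names(extra)) {
    extra[[field]](report)
  } else {
    abort(sprintf("unknown report field '%s'.", field))
  }
}

#' Contrast a report field between two conditions
#'
#' Extracts the named scalar from every report, groups by condition, and
#' runs [compare_groups()] (pairing is an explicit design input:
#' within-animal before/after contrasts are paired, across-group
#' contrasts unpaired). Reports missing the field are excluded with a
#' warning.
#'
#' @param reports list of [coupling_report()]s.
#' @param field a [glance.coupling_report()] column, or one of
#'   `"lc_early_magnitude"`, `"lc_late_magnitude"`, `"tcc_c_spikes"`.
#' @param grouping character vector of the two condition labels to
#'   compare, in order (x, y).
#' @param paired passed to [compare_groups()].
#' @param alpha_normality normality-gate level.
#' @return a `test_result` tibble (see [compare_groups()]).
#' @export
condition_contrast <- function(reports, field, grouping, paired = FALSE,
                               alpha_normality = 0.05) {
  stopifnot(length(grouping) == 2)
  vals <- vapply(reports, report_field, double(1), field = field)
  conds <- vapply(reports, function(r) r$condition, character(1))
  if (anyNA(vals)) {
    warn(sprintf("%d report(s) missing field '%s' were excluded.",
                 sum(is.na(vals)), field))
  }
  keep <- !is.na(vals)
  x <- vals[keep & conds == grouping[1]]
  y <- vals[keep & conds == grouping[2]]
  if (length(x) < 3 || length(y) < 3) {
    abort("need at least 3 reports per condition after exclusions.")
  }
  compare_groups(x, y, paired = paired, alpha_normality = alpha_normality)
}
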