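# Per-session coupling report: the summary object produced by
# run_coupling_analysis(), its JSON/Markdown serialisation, and
# broom-style tidiers.

#' Per-session coupling report
#'
#' Container for the per-session summary: evoked components per region,
#' oscillation periods, preferred phases and precession, delta-power
#' synchronization, LFP delta correlation (R^2 max) and lag, and the
#' LC/TCC evoked ratio. Analyses that were infeasible for the session
#' are `NULL`, with the reason recorded in the `reasons` field.
#'
#' @param evoked tibble of evoked components (with a `region` column),
#'   or `NULL`.
#' @param periods tibble with columns `region`, `rhythm`, `period`, or
#'   `NULL`.
#' @param preferred tibble with columns `region`, `rhythm`, `phase`, or
#'   `NULL`.
#' @param precession circular TCC - LC preferred-phase difference,
#'   radians in (-pi, pi], or `NULL`.
#' @param delta_ratio tibble with columns `region`, `ratio`, or `NULL`.
#' @param r2max max sliding-window R^2 between LFP delta power and the
#'   slow rate oscillation, in \[0, 1\], or `NULL`.
#' @param lfp_lag LFP cross-correlogram lag in seconds (positive = LC
#'   leads), or `NULL`.
#' @param lc_tcc_ratio LC early-component / TCC A-response ratio, or
#'   `NULL`.
#' @param condition condition label.
#' @param reasons named list of reasons for `NULL` fields.
#' @return list of class `coupling_report`.
#' @export
coupling_report <- function(evoked = NULL, periods = NULL, preferred = NULL,
                            precession = NULL, delta_ratio = NULL,
                            r2max = NULL, lfp_lag = NULL, lc_tcc_ratio = NULL,
                            condition = "naive", reasons = list()) {
  for (nm in c("precession")) {
    v <- get(nm)
    if (!is.null(v) && !is.na(v) && (v <= -pi - 1e-9 || v > pi + 1e-9)) {
      abort(sprintf("`%s` must be wrapped to (-pi, pi].", nm))
    }
  }
  for (nm in c("r2max")) {
    v <- get(nm)
    if (!is.null(v) && !is.na(v) && (v < 0 || v > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  structure(
    list(evoked = evoked, periods = periods, preferred = preferred,
         precession = precession, delta_ratio = delta_ratio, r2max = r2max,
         lfp_lag = lfp_lag, lc_tcc_ratio = lc_tcc_ratio,
         condition = condition, reasons = reasons),
    class = "coupling_report"
  )
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf("<coupling_report> condition '%s'\n", x$condition))
  g <- glance(x)
  for (nm in names(g)) {
    v <- g[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.na(v)) "NULL" else format(v, digits = 4)))
  }
  if (length(x$reasons)) {
    cat("  skipped:", paste(sprintf("%s (%s)", names(x$reasons),
                                    unlist(x$reasons)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
glance.coupling_report <- function(x, ...) {
  get_period <- function(region, rhythm) {
    if (is.null(x$periods)) return(NA_real_)
    v <- x$periods$period[x$periods$region == region & x$periods$rhythm == rhythm]
    if (length(v)) v[1] else NA_real_
  }
  tibble::tibble(
    condition = x$condition,
    lc_slow_period = get_period("LC", "slow"),
    lc_int_period = get_period("LC", "intermediate"),
    precession = x$precession %||% NA_real_,
    lc_delta_ratio = if (is.null(x$delta_ratio)) NA_real_ else {
      v <- x$delta_ratio$ratio[x$delta_ratio$region == "LC"]
      if (length(v)) v[1] else NA_real_
    },
    r2max = x$r2max %||% NA_real_,
    lfp_lag = x$lfp_lag %||% NA_real_,
    lc_tcc_ratio = x$lc_tcc_ratio %||% NA_real_
  )
}

#' @export
tidy.coupling_report <- function(x, ...) {
  g <- glance(x)
  tibble::tibble(term = setdiff(names(g), "condition"),
                 estimate = as.numeric(g[1, setdiff(names(g), "condition")]))
}

report_to_list <- function(report) {
  tbl_or_null <- function(x) if (is.null(x)) NULL else as.list(x)
  list(
    format = "duosync-report", version = 1L,
    condition = report$condition,
    evoked = tbl_or_null(report$evoked),
    periods = tbl_or_null(report$periods),
    preferred = tbl_or_null(report$preferred),
    precession = report$precession,
    delta_ratio = tbl_or_null(report$delta_ratio),
    r2max = report$r2max,
    lfp_lag = report$lfp_lag,
    lc_tcc_ratio = report$lc_tcc_ratio,
    reasons = report$reasons
  )
}

#' Write a coupling report to disk
#'
#' Writes both a machine-readable JSON file (`<path>.json`, null markers
#' for absent fields, reparsable by [read_report()]) and a human-readable
#' Markdown summary table (`<path>.md`).
#'
#' @param report a [coupling_report()].
#' @param path output path without extension (or with `.json`, which is
#'   stripped).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "coupling_report"))
  path <- sub("\\.(json|md)$", "", path)
  jsonlite::write_json(report_to_list(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  g <- glance(report)
  fmt <- function(v) if (is.na(v)) "—" else format(v, digits = 5)
  lines <- c(
    sprintf("# Coupling report (%s)", report$condition),
    "",
    "| quantity | value |",
    "|---|---|",
    vapply(setdiff(names(g), "condition"), function(nm) {
      sprintf("| %s | %s |", nm, fmt(g[[nm]]))
    }, character(1))
  )
  if (length(report$reasons)) {
    lines <- c(lines, "",
               sprintf("Skipped: %s.",
                       paste(sprintf("%s (%s)", names(report$reasons),
                                     unlist(report$reasons)), collapse = "; ")))
  }
  writeLines(lines, paste0(path, ".md"))
  invisible(path)
}

#' Read a coupling report written by [write_report()]
#' @param path path to the `.json` file (extension optional).
#' @return a [coupling_report()].
#' @export
read_report <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "duosync-report")) {
    abort(sprintf("'%s' is not a coupling report.", path))
  }
  as_tbl <- function(v) if (is.null(v)) NULL else tibble::as_tibble(v)
  coupling_report(
    evoked = as_tbl(x$evoked), periods = as_tbl(x$periods),
    preferred = as_tbl(x$preferred), precession = x$precession,
    delta_ratio = as_tbl(x$delta_ratio), r2max = x$r2max,
    lfp_lag = x$lfp_lag, lc_tcc_ratio = x$lc_tcc_ratio,
    condition = x$condition,
    reasons = if (length(x$reasons)) as.list(x$reasons) else list()
  )
}
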