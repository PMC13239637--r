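#' Build parametric-modulation regressors from model predictions
#'
#' For one experimental phase, CS events (all trial types grouped together)
#' are weighted by the ensemble-mean US prediction `v_t`, and US/no-US events
#' (7.9 s after CS onset; the no-US marker on unreinforced trials) by the
#' ensemble-mean absolute prediction error `|delta_t|`. All event durations
#' are 0 s and each weight set is mean-centered.
#'
#' @param trace per-trial ensemble trace (an `ensemble_trace` or its `trace`
#'   data.frame with columns `v` and `abs_delta`), aligned row-by-row with
#'   the design events.
#' @param design the `fear_design` supplying onsets (absolute session clock).
#' @param phase phase name to export.
#' @return list of two data.frames (`cs`, `us`), each with columns `onset`,
#'   `duration` (all 0) and `weight` (mean-centered), rows ordered by onset.
#' @export
build_modulators <- function(trace, design, phase) {
  tr <- if (is.data.frame(trace)) trace else trace$trace
  events <- design$events
  if (nrow(tr) != nrow(events))
    stop("trace and design have different trial counts")
  sel <- events$phase == phase
  if (!any(sel)) stop("phase not present in design: ", phase)
  demean <- function(w) w - mean(w)
  cs <- data.frame(onset = events$onset_abs[sel], duration = 0,
                   weight = demean(tr$v[sel]))
  us <- data.frame(onset = events$us_onset_abs[sel], duration = 0,
                   weight = demean(tr$abs_delta[sel]))
  list(cs = cs[order(cs$onset), , drop = FALSE],
       us = us[order(us$onset), , drop = FALSE])
}

#' Write / read FSL 3-column EV files
#'
#' Whitespace-delimited three columns (onset, duration, weight), one row per
#' event, fixed 6-decimal format; `read_fsl_ev3` round-trips bit-exactly with
#' `write_fsl_ev3`.
#'
#' @param events data.frame with columns `onset`, `duration`, `weight`.
#' @param path file path.
#' @export
write_fsl_ev3 <- function(events, path) {
  lines <- sprintf("%.6f %.6f %.6f", events$onset, events$duration,
                   events$weight)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fsl_ev3
#' @return for `read_fsl_ev3`, a data.frame with `onset`, `duration`,
#'   `weight` (empty if the file has no rows).
#' @export
read_fsl_ev3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      weight = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"),
                             as.numeric))
  data.frame(onset = m[, 1], duration = m[, 2], weight = m[, 3])
}

#' Export all parametric modulators of a fitted model
#'
#' Writes one EV file per (sequence, phase, event class) plus a JSON manifest.
#'
#' @param fit a `replay_fit`.
#' @param dir output directory (created if needed).
#' @param phases phases to export.
#' @return data.frame manifest (also written as `manifest.json`).
#' @export
export_modulators <- function(fit, dir,
                              phases = c("habituation", "acquisition",
                                         "extinction", "recall")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (l in fit$sequences) {
    for (ph in phases) {
      mods <- build_modulators(fit$ensembles[[l]], fit$designs[[l]], ph)
      for (cls in names(mods)) {
        fn <- sprintf("seq%s_%s_%s.txt", l, ph,
                      if (cls == "cs") "cs_prediction" else "us_abs_pe")
        write_fsl_ev3(mods[[cls]], file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = l, phase = ph,
          event_class = if (cls == "cs") "CS" else "US/no-US",
          modulator = if (cls == "cs") "mean prediction" else
            "mean |prediction error|",
          n_events = nrow(mods[[cls]]), file = fn,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
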