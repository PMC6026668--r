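#' Output phase pattern of a run
#'
#' The computation's result is the pattern of arrival times at the network's
#' terminals. Returns one sorted numeric vector of arrival times (s) per
#' requested terminal; terminals that saw no exits yield empty vectors.
#'
#' @param log an [EventLog-class].
#' @param terminalIds character vector of terminal node ids; defaults to the
#'   graph's TERMINAL nodes as echoed in the log config.
#' @return named list of sorted numeric vectors.
#' @examples
#' g <- generateChain(1, 100)
#' log <- simulatePulses(g, stimulusSchedule("entry", 0), 1e-3)
#' outputPhasePattern(log)  # $terminal: 1e-4
#' @export
outputPhasePattern <- function(log, terminalIds = NULL) {
  stopifnot(is(log, "EventLog"))
  known <- union(log@config$terminals, names(log@arrivals))
  if (is.null(terminalIds)) terminalIds <- log@config$terminals
  bad <- setdiff(terminalIds, known)
  if (length(bad))
    stop("unknown terminal id: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(terminalIds, function(n) {
    a <- log@arrivals[[n]]
    if (is.null(a)) numeric(0) else sort(a)
  })
  stats::setNames(out, terminalIds)
}

# Canonical textual form of an event log: fixed column order and float
# formatting so that identical runs serialize byte-identically.
.canonicalEventLines <- function(log) {
  e <- log@events
  if (!nrow(e)) return(character(0))
  vapply(seq_len(nrow(e)), function(i) {
    jsonlite::toJSON(
      list(time_s = e$time_s[i], kind = e$kind[i], pulses = e$pulses[i],
           node = e$node[i], segment = e$segment[i],
           position_um = e$position_um[i], label = e$label[i]),
      auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
}

#' Write an event log
#'
#' `writeEventLog` writes one JSON object per event (JSONL) with canonical
#' key order and full-precision floats, followed by nothing else;
#' `writeEventSummary` writes the conservation counters as a two-column CSV.
#' Both embed nothing beyond the log itself; the resolved run configuration
#' is available in `log@config`.
#'
#' @param log an [EventLog-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeEventLog <- function(log, path) {
  stopifnot(is(log, "EventLog"))
  writeLines(.canonicalEventLines(log), path)
  invisible(path)
}

#' @rdname writeEventLog
#' @export
writeEventSummary <- function(log, path) {
  stopifnot(is(log, "EventLog"))
  ct <- counters(log)
  utils::write.csv(data.frame(counter = names(ct), value = as.numeric(ct)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Raster plot of terminal arrivals
#'
#' One row per terminal, one tick per arrival, time in microseconds.
#'
#' @param log an [EventLog-class].
#' @param terminalIds terminals to show; defaults to all in the log.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the arrival pattern used.
#' @export
plotRaster <- function(log, terminalIds = NULL, ...) {
  pat <- outputPhasePattern(log, terminalIds)
  n <- length(pat)
  allT <- unlist(pat)
  xlim <- if (length(allT)) range(allT) * 1e6 else c(0, 1)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5),
                 xlab = "arrival time (us)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(n), labels = names(pat), las = 1)
  for (i in seq_len(n)) {
    ti <- pat[[i]] * 1e6
    if (length(ti))
      graphics::segments(ti, i - 0.3, ti, i + 0.3, lwd = 2)
  }
  invisible(pat)
}
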