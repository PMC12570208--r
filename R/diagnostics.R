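## Event-log instrumentation and the "computational weather plot":
## per-worker task-completion times, written as crash-tolerant plain text
## (one tab-separated line per event, flushed at once), rendered as a
## worker-by-time scatter.

#' Open an event log
#'
#' Creates (or appends to) a tab-separated event log with columns
#' \code{worker}, \code{generation}, \code{label}, \code{seconds}. Each
#' event is written as one line and flushed immediately, so the file stays
#' parseable line-by-line even after an abrupt termination.
#'
#' @param path log file path; the directory must be writable (checked at
#'   open time, never mid-run).
#' @param t0 reference wall-clock origin (defaults to now).
#' @export
event_log <- function(path, t0 = Sys.time()) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(errorCondition(sprintf("event log directory '%s' is not writable", dir),
                        class = c("spimtip_io_error", "spimtip_error")))
  if (!file.exists(path)) file.create(path)
  structure(list(path = path, t0 = t0), class = "event_log")
}

#' Record a task-completion event
#'
#' @param log an [event_log()].
#' @param worker integer worker id.
#' @param label short task label (no tabs or newlines).
#' @param generation generation counter.
#' @param seconds wall time since the log origin; defaults to now.
#' @return the log, invisibly.
#' @export
record_event <- function(log, worker, label, generation,
                         seconds = as.numeric(difftime(Sys.time(), log$t0, units = "secs"))) {
  if (!inherits(log, "event_log")) stop_param("log must be an event_log")
  label <- gsub("[\t\n]", " ", as.character(label)[1])
  line <- sprintf("%d\t%d\t%s\t%.6f", as.integer(worker), as.integer(generation),
                  label, seconds)
  con <- file(log$path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  flush(con)
  invisible(log)
}

#' Parse an event log
#'
#' Malformed (e.g. truncated) trailing lines are dropped with a warning
#' rather than corrupting the parse.
#'
#' @param path log file path (or an [event_log()]).
#' @return data frame with columns worker, generation, label, seconds.
#' @export
read_event_log <- function(path) {
  if (inherits(path, "event_log")) path <- path$path
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) == 4 && !is.na(suppressWarnings(as.numeric(p[4]))), TRUE)
  if (any(!ok)) warning(sprintf("dropped %d malformed event line(s)", sum(!ok)))
  parts <- parts[ok]
  data.frame(worker = as.integer(vapply(parts, `[`, "", 1)),
             generation = as.integer(vapply(parts, `[`, "", 2)),
             label = vapply(parts, `[`, "", 3),
             seconds = as.numeric(vapply(parts, `[`, "", 4)))
}

#' Computational weather plot
#'
#' One row per worker, one point per completed task at its wall-clock
#' completion time: stalls, stragglers and I/O contention show up as gaps
#' or short rows at a glance.
#'
#' @param log an [event_log()], a log path, or a parsed event data frame.
#' @param file output PNG path.
#' @param width,height figure size in pixels.
#' @return invisibly, the plotted data frame (deterministic for a fixed log).
#' @export
weather_plot <- function(log, file, width = 900, height = 450) {
  ev <- if (is.data.frame(log)) log else read_event_log(log)
  if (nrow(ev) == 0) stop_param("event log is empty")
  workers <- sort(unique(ev$worker))
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::plot(ev$seconds, match(ev$worker, workers),
                 pch = 20, cex = 0.5, col = "forestgreen",
                 xlab = "wall time [s]", ylab = "worker",
                 yaxt = "n", main = "computational weather")
  graphics::axis(2, at = seq_along(workers), labels = workers)
  invisible(ev)
}
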