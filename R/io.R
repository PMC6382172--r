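# Delimited-text readers/writers shared by all analyses.
# Times are in ms unless a header or '# units: s' comment declares seconds;
# '#' lines are comments throughout.

read_event_column <- function(path, what = "event") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  unit <- "ms"
  um <- grepl("^#\\s*units?\\s*:\\s*s(ec(onds)?)?\\s*$", raw,
              ignore.case = TRUE)
  if (any(um)) unit <- "s"
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop(sprintf("%s: no events found (file empty or all comments)", path))
  # optional single-token header declaring the unit
  first <- trimws(lines[1])
  if (suppressWarnings(is.na(as.numeric(first)))) {
    if (grepl("(_|\\b)s(ec)?(\\b|$)", first, ignore.case = TRUE) &&
        !grepl("ms", first, ignore.case = TRUE))
      unit <- "s"
    lines <- lines[-1]
    lineno <- lineno[-1]
    if (length(lines) == 0L)
      stop(sprintf("%s: no events found below the header", path))
  }
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  if (any(is.na(vals) | !is.finite(vals))) {
    bad <- lineno[which(is.na(vals) | !is.finite(vals))[1]]
    stop(sprintf("%s: line %d does not parse as a finite %s time",
                 path, bad, what))
  }
  if (unit == "s") vals <- vals * 1000
  vals
}

#' Read a spike-time file
#'
#' One spike time per row, in ms (or seconds when declared by a header
#' token containing `s`/`sec`, or a `# units: s` comment). `#` lines are
#' comments. Malformed or non-monotonic rows raise errors naming the file
#' and line.
#'
#' @param path file path.
#' @param window optional recording window in ms; defaults to the span of
#'   the spikes.
#' @return A [spike_train()].
#' @export
read_spike_file <- function(path, window = NULL) {
  v <- read_event_column(path, "spike")
  if (is.unsorted(v, strictly = TRUE))
    stop(sprintf("%s: spike times are not strictly increasing", path))
  if (is.null(window)) spike_train(v) else spike_train(v, window = window)
}

#' Read a pulse-onset file
#'
#' Same format as [read_spike_file()]. The pulse width is taken from a
#' `# width_ms: <x>` comment when present, otherwise from the `width_ms`
#' argument.
#'
#' @param path file path.
#' @param width_ms pulse width in ms used when the file declares none.
#' @return A [pulse_train()].
#' @export
read_pulse_file <- function(path, width_ms = 0.5) {
  raw <- readLines(path, warn = FALSE)
  wm <- regmatches(raw, regexec("^#\\s*width_ms\\s*:\\s*([0-9.eE+-]+)", raw))
  ws <- Filter(length, wm)
  if (length(ws)) width_ms <- as.numeric(ws[[1]][2])
  pulse_train(read_event_column(path, "pulse"), width = width_ms)
}

#' Read a sampled two-column trace
#'
#' Comma- or whitespace-delimited text with columns time and value (header
#' optional: `time_ms,value` or `time_s,value`). Sampling must be uniform
#' within a relative tolerance of 1e-9.
#'
#' @param path file path.
#' @return A data frame with columns `time_ms` and `value`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop(sprintf("%s: empty trace", path))
  in_s <- FALSE
  first <- strsplit(trimws(lines[1]), "[,\\s]+", perl = TRUE)[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first))))) {
    in_s <- grepl("time_s\\b|\\(s\\)", lines[1], ignore.case = TRUE)
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) < 3L) stop(sprintf("%s: trace too short", path))
  parts <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2L))
    stop(sprintf("%s: line %d does not have two columns",
                 path, lineno[which(nc != 2L)[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L,
              byrow = TRUE)
  if (any(!is.finite(m)))
    stop(sprintf("%s: line %d does not parse as finite numbers",
                 path, lineno[which(rowSums(!is.finite(m)) > 0)[1]]))
  t <- if (in_s) m[, 1] * 1000 else m[, 1]
  dts <- diff(t)
  if (any(abs(dts - stats::median(dts)) > 1e-9 * max(abs(stats::median(dts)), 1)))
    stop(sprintf("%s: sampling is not uniform", path))
  data.frame(time_ms = t, value = m[, 2])
}

#' Write event times to a delimited-text file
#'
#' @param x a [spike_train()] or [pulse_train()], or numeric times in ms.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_event_file <- function(x, path) {
  hdr <- character(0)
  if (inherits(x, "pulse_train")) {
    hdr <- sprintf("# width_ms: %.17g", x$width)
    v <- x$onsets
  } else if (inherits(x, "spike_train")) {
    hdr <- sprintf("# window_ms: %.17g %.17g", x$window[1], x$window[2])
    v <- x$times
  } else v <- x
  writeLines(c(hdr, "time_ms", sprintf("%.17g", v)), path)
  invisible(path)
}

#' Write a sampled trace to a delimited-text file
#'
#' @param trace data frame with columns `time_ms` and `value`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace),
            all(c("time_ms", "value") %in% names(trace)))
  writeLines(c("time_ms,value",
               sprintf("%.17g,%.17g", trace$time_ms, trace$value)), path)
  invisible(path)
}

#' Write an analysis record as JSON
#'
#' Serializes a (possibly nested) list of results to JSON with full numeric
#' precision, embedding the package version for provenance.
#'
#' @param record named list of results.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_results <- function(record, path) {
  stopifnot(is.list(record))
  record$package <- paste0("dendrophase ",
                           as.character(utils::packageVersion("dendrophase")))
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
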