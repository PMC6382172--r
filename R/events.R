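#' Spike train of a single cell or trial
#'
#' @param times spike times in ms, strictly increasing.
#' @param window recording window `c(t_start, t_end)` in ms containing all
#'   spikes; defaults to the span of the spikes.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times, window = range(times)) {
  stopifnot(is.numeric(times), length(times) >= 1L, all(is.finite(times)),
            is.numeric(window), length(window) == 2L, window[1] <= window[2])
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (times[1] < window[1] || times[length(times)] > window[2])
    stop("spike times fall outside the recording window")
  structure(list(times = times, window = window), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$times)
  dur <- diff(x$window) / 1000
  cat(sprintf("Spike train: %d spikes over %.3g s (%.3g spikes/s)\n",
              n, dur, n / dur))
  invisible(x)
}

#' Optogenetic pulse train
#'
#' @param onsets pulse onset times in ms, increasing. A pulse's timestamp is
#'   its onset (inter-pulse intervals run onset to onset).
#' @param width pulse duration in ms (positive). Successive onsets must be
#'   separated by at least one pulse width.
#' @return An object of class `"pulse_train"`.
#' @export
pulse_train <- function(onsets, width = 0.5) {
  stopifnot(is.numeric(onsets), all(is.finite(onsets)),
            is.numeric(width), length(width) == 1L, width > 0)
  if (length(onsets) > 1L) {
    if (is.unsorted(onsets)) stop("pulse onsets must be increasing")
    if (any(diff(onsets) < width))
      stop("inter-pulse intervals must be at least one pulse width")
  }
  structure(list(onsets = onsets, width = width), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("Pulse train: %d pulses, width %g ms", length(x$onsets), x$width))
  if (length(x$onsets) > 1L)
    cat(sprintf(", mean IPI %.3g ms", mean(diff(x$onsets))))
  cat("\n")
  invisible(x)
}
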