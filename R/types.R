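#' Raw accelerometer trace
#'
#' Container for one participant's raw 3-axis accelerometer stream in one
#' conversation: a regularly sampled data frame with columns `t_s`, `x`,
#' `y`, `z` plus identifying attributes.
#'
#' @param t_s Numeric vector of timestamps in seconds, strictly increasing
#'   and regular at `1 / sample_rate_hz`.
#' @param x,y,z Numeric vectors of per-axis acceleration in sensor units.
#' @param participant Participant identifier (e.g. `"a"` or `"b"`).
#' @param conversation Conversation identifier (1 or 2).
#' @param sample_rate_hz Nominal sampling rate in Hz (default 250).
#'
#' @return An object of class `accel_trace`: a data frame with columns
#'   `t_s`, `x`, `y`, `z` and attributes `participant`, `conversation`,
#'   `sample_rate_hz`.
#' @export
accel_trace <- function(t_s, x, y, z, participant = NA, conversation = NA,
                        sample_rate_hz = 250) {
  n <- length(t_s)
  stopifnot(length(x) == n, length(y) == n, length(z) == n, n >= 2)
  dt <- diff(t_s)
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing (first violation at row ",
         which(dt <= 0)[1] + 1L, ")")
  }
  period <- 1 / sample_rate_hz
  if (max(abs(dt - period)) >= period / 2) {
    stop("irregular sampling: timestamp jitter exceeds half a sample period")
  }
  out <- data.frame(t_s = t_s, x = x, y = y, z = z)
  structure(out,
            participant = participant,
            conversation = conversation,
            sample_rate_hz = sample_rate_hz,
            class = c("accel_trace", "data.frame"))
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "<accel_trace> participant=%s conversation=%s | %d samples @ %g Hz (%.1f s)\n",
    attr(x, "participant"), attr(x, "conversation"),
    nrow(x), attr(x, "sample_rate_hz"), nrow(x) / attr(x, "sample_rate_hz")))
  invisible(x)
}

#' Duration of a trace or series in seconds
#'
#' @param x An `accel_trace` or `movement_series`.
#' @return Duration in seconds (`n / sample_rate`).
#' @export
duration_s <- function(x) {
  nrow(x) / attr(x, "sample_rate_hz")
}

#' Scalar movement series
#'
#' A filtered, downsampled scalar acceleration series at (by default) 10 Hz,
#' the unit of analysis for cross-recurrence. Provenance flags record which
#' preprocessing stages have been applied.
#'
#' @param t_s Timestamps in seconds.
#' @param a Scalar acceleration magnitude (sensor units).
#' @param participant,conversation Identifiers carried along from the trace.
#' @param sample_rate_hz Sampling rate, 10 Hz after downsampling.
#' @param filtered,smoothed,trimmed Logical provenance flags.
#'
#' @return An object of class `movement_series` (a data frame with columns
#'   `t_s`, `a`).
#' @export
movement_series <- function(t_s, a, participant = NA, conversation = NA,
                            sample_rate_hz = 10, filtered = FALSE,
                            smoothed = FALSE, trimmed = FALSE) {
  stopifnot(length(t_s) == length(a))
  out <- data.frame(t_s = t_s, a = a)
  structure(out,
            participant = participant,
            conversation = conversation,
            sample_rate_hz = sample_rate_hz,
            filtered = filtered, smoothed = smoothed, trimmed = trimmed,
            class = c("movement_series", "data.frame"))
}

#' @export
print.movement_series <- function(x, ...) {
  flags <- c("filtered", "smoothed", "trimmed")
  on <- flags[vapply(flags, function(f) isTRUE(attr(x, f)), logical(1))]
  cat(sprintf(
    "<movement_series> participant=%s conversation=%s | %d samples @ %g Hz%s\n",
    attr(x, "participant"), attr(x, "conversation"),
    nrow(x), attr(x, "sample_rate_hz"),
    if (length(on)) paste0(" [", paste(on, collapse = ","), "]") else ""))
  invisible(x)
}

# Rebuild a movement_series with new data, keeping identity attributes.
ms_update <- function(series, t_s, a, ...) {
  dots <- list(...)
  flag <- function(name) {
    if (!is.null(dots[[name]])) dots[[name]] else isTRUE(attr(series, name))
  }
  movement_series(
    t_s, a,
    participant = attr(series, "participant"),
    conversation = attr(series, "conversation"),
    sample_rate_hz = if (!is.null(dots$sample_rate_hz)) dots$sample_rate_hz
                     else attr(series, "sample_rate_hz"),
    filtered = flag("filtered"), smoothed = flag("smoothed"),
    trimmed = flag("trimmed"))
}
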