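# Zero-phase Butterworth filtering with odd-reflection edge padding.
# Forward-backward application squares the magnitude response (effective
# order doubles) and cancels the phase.
butter_zerophase <- function(x, order, cutoff_hz, fs) {
  n <- length(x)
  if (n < 3 * order) {
    stop("series too short for order-", order, " zero-phase filtering (",
         n, " < ", 3 * order, " samples)")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  dc <- sum(bf$b) / sum(bf$a)
  run1 <- function(v) {
    # steady-state initial conditions at the first sample, so the filter
    # has no startup transient (a constant series passes unchanged)
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], length(bf$b) - 1L),
                              init.y = rep(v[1] * dc, length(bf$a) - 1L)))
  }
  pl <- min(n - 1L, 9L * order)
  pad <- c(2 * x[1] - x[(pl + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - pl)])
  y <- run1(pad)
  y <- rev(run1(rev(y)))
  y[(pl + 1):(pl + n)]
}

#' Anti-aliasing filter for raw accelerometer traces
#'
#' Applies a zero-phase fourth-order low-pass Butterworth filter to each
#' axis, by default with the 5 Hz cutoff that protects a subsequent
#' decimation to 10 Hz. Zero phase is achieved by forward-backward
#' application with odd-reflection padding at the edges.
#'
#' @param trace An [accel_trace()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 5, the post-decimation
#'   Nyquist frequency).
#' @param order Filter order per pass (default 4).
#'
#' @return The filtered trace.
#' @export
antialias_filter <- function(trace, cutoff_hz = 5, order = 4) {
  fs <- attr(trace, "sample_rate_hz")
  for (ax in c("x", "y", "z")) {
    trace[[ax]] <- butter_zerophase(trace[[ax]], order, cutoff_hz, fs)
  }
  attr(trace, "antialiased") <- TRUE
  trace
}

#' Decimate a trace to a lower sampling rate
#'
#' Keeps every k-th sample (k = original rate / target rate); the
#' anti-aliasing filter must already have been applied. Non-integer
#' decimation ratios are rejected rather than resampled.
#'
#' @param trace An [accel_trace()] (already anti-alias filtered).
#' @param target_hz Target rate in Hz (default 10).
#'
#' @return The decimated trace, original timestamps preserved.
#' @export
downsample <- function(trace, target_hz = 10) {
  fs <- attr(trace, "sample_rate_hz")
  k <- fs / target_hz
  if (abs(k - round(k)) > 1e-9) {
    stop("sampling rate ", fs, " Hz is not an integer multiple of the ",
         target_hz, " Hz target; non-integer decimation is not supported")
  }
  k <- as.integer(round(k))
  idx <- seq(1L, nrow(trace), by = k)
  out <- trace[idx, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(trace)
  attrs$row.names <- attr(out, "row.names")
  attrs$sample_rate_hz <- target_hz
  attributes(out) <- attrs
  out
}

#' Collapse a 3-axis trace to scalar acceleration
#'
#' The per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three axes.
#'
#' @param trace An [accel_trace()].
#' @return A [movement_series()] with `a >= 0`.
#' @export
euclidean_acceleration <- function(trace) {
  a <- sqrt(trace$x^2 + trace$y^2 + trace$z^2)
  movement_series(trace$t_s, a,
                  participant = attr(trace, "participant"),
                  conversation = attr(trace, "conversation"),
                  sample_rate_hz = attr(trace, "sample_rate_hz"),
                  filtered = isTRUE(attr(trace, "antialiased")))
}

#' Smooth a scalar acceleration series
#'
#' Zero-phase second-order low-pass Butterworth smoothing of the 10 Hz
#' scalar acceleration, default cutoff 2 Hz: slow head-movement dynamics
#' (nods, shakes, sway) pass, sensor jitter is removed.
#'
#' @param series A [movement_series()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 2).
#' @param order Filter order per pass (default 2).
#'
#' @return The smoothed series.
#' @export
smooth_series <- function(series, cutoff_hz = 2, order = 2) {
  fs <- attr(series, "sample_rate_hz")
  a <- butter_zerophase(series$a, order, cutoff_hz, fs)
  ms_update(series, series$t_s, a, smoothed = TRUE)
}

#' Jerk and jounce of an acceleration series
#'
#' First (jerk) and second (jounce) time-derivatives by central finite
#' differences scaled by the sampling interval; endpoints use one-sided
#' differences so the outputs keep the input's length and timestamps.
#'
#' @param series A [movement_series()] with at least 3 samples.
#' @return A list with `jerk` and `jounce`, both [movement_series()]
#'   (in units of sensor-units/s and sensor-units/s^2).
#' @export
derivatives <- function(series) {
  n <- nrow(series)
  if (n < 3) stop("need at least 3 samples to differentiate, got ", n)
  fs <- attr(series, "sample_rate_hz")
  d1 <- function(v) {
    out <- numeric(length(v))
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
    out[1] <- (v[2] - v[1]) * fs
    out[n] <- (v[n] - v[n - 1]) * fs
    out
  }
  jerk <- d1(series$a)
  jounce <- d1(jerk)
  list(jerk = ms_update(series, series$t_s, jerk),
       jounce = ms_update(series, series$t_s, jounce))
}

#' Dyad-level calibration cutoff from jounce
#'
#' Each participant performs a burst of rapid head movement while testing
#' the equipment 60-120 s into the recording; the latest moment of intense
#' movement marks where the conversation proper begins. Per participant the
#' candidate cutoff is the time of largest |jounce| (and, for comparison,
#' largest |jerk|) within the window, ties broken by the latest time; the
#' dyad-level cutoff is the later (more conservative) of the two
#' participants' jounce cutoffs.
#'
#' @param series_a,series_b The two participants' smoothed
#'   [movement_series()], each covering at least the window end.
#' @param window Search window in seconds, default `c(60, 120)`.
#'
#' @return An object of class `cutoff_result`: per-participant jerk and
#'   jounce cutoffs and the dyad cutoff, all in seconds.
#' @export
find_dyad_cutoff <- function(series_a, series_b, window = c(60, 120)) {
  for (s in list(series_a, series_b)) {
    if (max(s$t_s) < window[2]) {
      stop("calibration window [", window[1], ", ", window[2],
           "] s exceeds series length (", round(max(s$t_s), 2), " s)")
    }
  }
  argmax_time <- function(series, deriv) {
    d <- derivatives(series)[[deriv]]
    sel <- d$t_s >= window[1] & d$t_s <= window[2]
    v <- abs(d$a[sel])
    tt <- d$t_s[sel]
    # latest time among ties
    max(tt[v == max(v)])
  }
  res <- list(
    jerk_a = argmax_time(series_a, "jerk"),
    jerk_b = argmax_time(series_b, "jerk"),
    jounce_a = argmax_time(series_a, "jounce"),
    jounce_b = argmax_time(series_b, "jounce"))
  res$dyad <- max(res$jounce_a, res$jounce_b)
  structure(res, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> jounce a=%.1fs b=%.1fs -> dyad %.1fs (jerk a=%.1fs b=%.1fs)\n",
              x$jounce_a, x$jounce_b, x$dyad, x$jerk_a, x$jerk_b))
  invisible(x)
}

#' Trim to the cutoff and truncate to equal length
#'
#' Drops everything before the dyad cutoff from both participants' series,
#' then truncates both to the shorter of the two remaining lengths so the
#' pair is sample-aligned.
#'
#' @param series_a,series_b [movement_series()] pair.
#' @param cutoff_s Dyad-level cutoff in seconds.
#'
#' @return A list with equal-length `a` and `b`.
#' @export
trim_and_truncate <- function(series_a, series_b, cutoff_s) {
  cut1 <- function(s) s[s$t_s >= cutoff_s, , drop = FALSE]
  keep_attrs <- function(out, s) {
    attrs <- attributes(s)
    attrs$row.names <- seq_len(nrow(out))
    attrs$trimmed <- TRUE
    attributes(out) <- attrs
    out
  }
  a <- cut1(series_a)
  b <- cut1(series_b)
  n <- min(nrow(a), nrow(b))
  if (n < 1) {
    stop("cutoff at ", cutoff_s, " s leaves no samples in at least one series")
  }
  list(a = keep_attrs(a[seq_len(n), , drop = FALSE], series_a),
       b = keep_attrs(b[seq_len(n), , drop = FALSE], series_b))
}

#' Study-level inclusion rule
#'
#' A dyad is retained only if all four participant-conversation traces
#' contain at least `min_keep_s` seconds of recorded data (inclusive bound),
#' calibration period included.
#'
#' @param study A `dyad_study`.
#' @param min_keep_s Minimum raw duration in seconds (default 270 = 4.5 min).
#'
#' @return Logical vector, one element per dyad.
#' @export
inclusion_filter <- function(study, min_keep_s = 270) {
  vapply(study$dyads, function(rec) {
    durs <- unlist(lapply(rec$conversations, function(cv) {
      c(duration_s(cv$a), duration_s(cv$b))
    }))
    all(durs >= min_keep_s)
  }, logical(1))
}

#' Preprocess one conversation's trace pair
#'
#' Runs the full preparation chain in order: anti-alias filter, decimation
#' to `target_hz`, Euclidean acceleration, smoothing, jounce-based dyad
#' cutoff within `window`, and trim/truncate to an aligned pair.
#'
#' @param trace_a,trace_b The two participants' raw [accel_trace()]s.
#' @param target_hz Analysis rate (default 10 Hz).
#' @param window Calibration search window in seconds.
#'
#' @return A list with aligned series `a`, `b` and the `cutoff`
#'   (`cutoff_result`).
#' @export
preprocess_conversation <- function(trace_a, trace_b, target_hz = 10,
                                    window = c(60, 120)) {
  prep1 <- function(tr) {
    tr |> antialias_filter() |> downsample(target_hz) |>
      euclidean_acceleration() |> smooth_series()
  }
  a <- prep1(trace_a)
  b <- prep1(trace_b)
  cut <- find_dyad_cutoff(a, b, window)
  pair <- trim_and_truncate(a, b, cut$dyad)
  stopifnot(nrow(pair$a) == nrow(pair$b))
  list(a = pair$a, b = pair$b, cutoff = cut)
}

#' Preprocess every included dyad of a study
#'
#' Applies the inclusion rule, then [preprocess_conversation()] to each
#' retained dyad-conversation.
#'
#' @param study A `dyad_study` from [simulate_study()] or assembled from
#'   CSVs via [read_study_csv()].
#' @param target_hz Analysis rate in Hz.
#' @param window Calibration search window in seconds.
#' @param min_keep_s Inclusion threshold in seconds.
#'
#' @return An object of class `prepped_study`: `conversations` (list of
#'   preprocessed pairs with metadata), `cutoffs` (data frame), and the
#'   inclusion flags.
#' @export
preprocess_study <- function(study, target_hz = 10, window = c(60, 120),
                             min_keep_s = 270) {
  keep <- inclusion_filter(study, min_keep_s)
  conversations <- list()
  cut_rows <- list()
  for (d in which(keep)) {
    rec <- study$dyads[[d]]
    for (cv in rec$conversations) {
      pp <- preprocess_conversation(cv$a, cv$b, target_hz, window)
      conversations[[length(conversations) + 1]] <- list(
        dyad = rec$dyad, conversation = cv$conv_num,
        conv_type = cv$conv_type, task = rec$task,
        a = pp$a, b = pp$b, cutoff = pp$cutoff)
      cut_rows[[length(cut_rows) + 1]] <- data.frame(
        dyad = rec$dyad, conversation = cv$conv_num,
        cutoff_a = pp$cutoff$jounce_a, cutoff_b = pp$cutoff$jounce_b,
        cutoff_dyad = pp$cutoff$dyad)
    }
  }
  structure(list(conversations = conversations,
                 cutoffs = do.call(rbind, cut_rows),
                 included = keep),
            class = "prepped_study")
}

#' @export
print.prepped_study <- function(x, ...) {
  cat(sprintf("<prepped_study> %d conversations from %d included dyads\n",
              length(x$conversations), sum(x$included)))
  invisible(x)
}
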