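#' Study design for a simulated dyadic conversation experiment
#'
#' Describes the factorial layout of a two-conversation dyadic study: every
#' dyad holds one affiliative and one argumentative conversation
#' (within-dyads, order counterbalanced across dyads), under a single
#' between-dyads task condition (dual-task or noise). Defaults mirror a
#' 21-dyad study with 9 noise and 12 dual-task dyads and 8-minute
#' conversations sampled at 250 Hz.
#'
#' @param n_dyads Number of dyads (>= 1).
#' @param n_noise Number of dyads assigned to the noise condition; the rest
#'   are dual-task. Default keeps the 9:12 noise:dual-task ratio.
#' @param conversation_duration_s Nominal conversation length in seconds.
#' @param sample_rate_hz Accelerometer sampling rate in Hz.
#' @param seed Integer seed used by [simulate_study()].
#'
#' @return An object of class `study_design`: per-dyad task assignments and
#'   counterbalanced conversation orders.
#' @export
study_design <- function(n_dyads = 21, n_noise = round(n_dyads * 9 / 21),
                         conversation_duration_s = 480,
                         sample_rate_hz = 250, seed = 1L) {
  stopifnot(n_dyads >= 1, n_noise >= 0, n_noise <= n_dyads,
            conversation_duration_s > 0, sample_rate_hz > 0)
  task <- rep("dual-task", n_dyads)
  if (n_noise > 0) {
    task[unique(round(seq(1, n_dyads, length.out = n_noise)))] <- "noise"
  }
  # counterbalance conversation order to within one dyad
  first <- rep(c("affiliative", "argumentative"), length.out = n_dyads)
  orders <- lapply(first, function(f) {
    c(f, setdiff(c("affiliative", "argumentative"), f))
  })
  structure(list(n_dyads = n_dyads,
                 task = task,
                 conversation_order = orders,
                 conversation_duration_s = conversation_duration_s,
                 sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d dyads (%d noise / %d dual-task), %g s @ %g Hz, seed %d\n",
              x$n_dyads, sum(x$task == "noise"), sum(x$task == "dual-task"),
              x$conversation_duration_s, x$sample_rate_hz, x$seed))
  invisible(x)
}

#' Coupling specification for the movement generator
#'
#' Each participant's movement is generated as a latent drive: an AR(1)
#' process (persistence `drive_persistence` at the 10 Hz bout rate) pushed
#' toward `base_amplitude` whenever a two-state moving/still bout process is
#' in the moving state. Interpersonal coupling enters through the bout
#' process: `inphase_gain` cross-excites the partner's bouts (simultaneous
#' movement, recurrence peak at lag 0) while `turntaking_gain`
#' cross-inhibits them (alternating movement envelopes, a U-shaped diagonal
#' recurrence profile).
#'
#' @param base_amplitude Target drive amplitude while moving (sensor units).
#' @param drive_persistence AR(1) coefficient of the drive at 10 Hz.
#' @param p_move_on Baseline per-step (0.1 s) probability of starting a bout.
#' @param p_move_off Baseline per-step probability of ending a bout.
#' @param inphase_gain Coupling strength toward simultaneous movement (>= 0).
#' @param turntaking_gain Coupling strength toward alternation (>= 0).
#' @param noise_sd Per-axis white sensor noise SD (> 0, sensor units).
#' @param burst_amplitude Calibration-burst amplitude (sensor units); must
#'   dominate ordinary movement so the jounce detector can find it.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(base_amplitude = 1, drive_persistence = 0.9,
                          p_move_on = 0.03, p_move_off = 0.05,
                          inphase_gain = 0, turntaking_gain = 0,
                          noise_sd = 0.05, burst_amplitude = 10) {
  stopifnot(inphase_gain >= 0, turntaking_gain >= 0, noise_sd > 0,
            drive_persistence >= 0, drive_persistence < 1,
            p_move_on > 0, p_move_on < 1, p_move_off > 0, p_move_off < 1)
  structure(list(base_amplitude = base_amplitude,
                 drive_persistence = drive_persistence,
                 p_move_on = p_move_on, p_move_off = p_move_off,
                 inphase_gain = inphase_gain,
                 turntaking_gain = turntaking_gain,
                 noise_sd = noise_sd,
                 burst_amplitude = burst_amplitude),
            class = "coupling_spec")
}

#' Default condition-to-coupling map
#'
#' Maps each conversation type to coupling gains: affiliative conversations
#' couple in phase (synchrony, an inverted-U profile) and argumentative
#' conversations couple by turn-taking (alternation, a U-shaped profile)
#' with weaker in-phase coupling, so a study generated at these defaults has
#' higher recurrence in affiliative than argumentative conversations. The
#' same map is used in both task conditions.
#'
#' @return A data frame with columns `conv_type`, `task`, `inphase_gain`,
#'   `turntaking_gain`.
#' @export
default_coupling_map <- function() {
  expand.grid(conv_type = c("affiliative", "argumentative"),
              task = c("dual-task", "noise"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
    , c("conv_type", "task")] |>
    transform(inphase_gain = ifelse(conv_type == "affiliative", 8, 1),
              turntaking_gain = ifelse(conv_type == "affiliative", 0, 8))
}

#' Dropout specification
#'
#' Server-disconnect censoring: each participant-conversation trace is cut
#' to a prefix at an exponentially distributed disconnect time with hazard
#' `hazard_per_s`; a dyad is included only if all four traces retain at
#' least `min_keep_s` seconds.
#'
#' @param hazard_per_s Disconnect probability per second (0 <= h < 1).
#' @param min_keep_s Minimum retained duration in seconds (default 270 s,
#'   i.e. 4.5 min).
#'
#' @return An object of class `dropout_spec`.
#' @export
dropout_spec <- function(hazard_per_s = 0, min_keep_s = 270) {
  stopifnot(hazard_per_s >= 0, hazard_per_s < 1, min_keep_s > 0)
  structure(list(hazard_per_s = hazard_per_s, min_keep_s = min_keep_s),
            class = "dropout_spec")
}

# Coupled two-state bout processes at the coarse (10 Hz) rate.
# In-phase coupling pulls the pair toward the same state (partner movement
# excites my onsets, partner stillness promotes my offsets); turn-taking
# coupling is the mirror image and pulls toward alternation. The symmetric
# form keeps duty cycles balanced rather than saturating into permanent
# movement at strong gains.
simulate_bouts <- function(n_steps, spec) {
  g_in <- spec$inphase_gain
  g_tt <- spec$turntaking_gain
  b <- matrix(0L, nrow = n_steps, ncol = 2)
  u <- matrix(stats::runif(2 * n_steps), nrow = n_steps, ncol = 2)
  b[1, ] <- as.integer(u[1, ] < 0.3)
  p_on0 <- spec$p_move_on
  p_off0 <- spec$p_move_off
  for (t in 2:n_steps) {
    for (i in 1:2) {
      pj <- b[t - 1, 3 - i]
      if (b[t - 1, i] == 0L) {
        p_on <- p_on0 * (1 + g_in * pj) * (1 + g_tt * (1 - pj))
        b[t, i] <- as.integer(u[t, i] < min(p_on, 0.5))
      } else {
        p_off <- p_off0 * (1 + g_in * (1 - pj)) * (1 + g_tt * pj)
        b[t, i] <- as.integer(u[t, i] >= min(p_off, 0.9))
      }
    }
  }
  b
}

# One participant's 3-axis trace from a bout sequence: AR(1) drive toward
# base_amplitude while moving, upsampled to the accelerometer rate,
# modulated by a band-limited oscillation and projected on a random axis
# orientation with white sensor noise.
drive_to_trace <- function(bouts, spec, duration_s, fs, coarse_hz,
                           participant, conversation) {
  n_coarse <- length(bouts)
  phi <- spec$drive_persistence
  innov <- (1 - phi) * spec$base_amplitude * bouts +
    stats::rnorm(n_coarse, sd = 0.02 * spec$base_amplitude)
  drive <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  drive <- pmax(drive, 0)

  n <- round(duration_s * fs)
  t_s <- seq(0, by = 1 / fs, length.out = n)
  t_coarse <- seq(0, by = 1 / coarse_hz, length.out = n_coarse)
  env <- stats::approx(t_coarse, drive, xout = t_s, rule = 2)$y

  # band-limited carrier: AR(1) at the sensor rate, unit variance
  phi_f <- 0.97
  osc <- as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi_f^2)),
                                  phi_f, method = "recursive"))
  sig <- env * osc

  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  xyz <- outer(sig, axis) + matrix(stats::rnorm(3 * n, sd = spec$noise_sd),
                                   ncol = 3)
  accel_trace(t_s, xyz[, 1], xyz[, 2], xyz[, 3],
              participant = participant, conversation = conversation,
              sample_rate_hz = fs)
}

#' Plant a calibration burst into a trace
#'
#' Adds a brief (2 s) high-amplitude, Hann-windowed oscillatory burst at
#' `t_burst_s`, emulating the rapid head nodding/shaking participants
#' perform during equipment testing 60-120 s into a recording. The burst's
#' jounce dominates the rest of the series so the cutoff detector can
#' recover its time.
#'
#' @param trace An [accel_trace()].
#' @param t_burst_s Burst center time in seconds, within \[60, 120\].
#' @param amplitude Burst amplitude in sensor units (> 0).
#' @param freq_hz Burst oscillation frequency (default 1.5 Hz, within the
#'   preprocessing passband).
#' @param width_s Burst duration in seconds.
#'
#' @return The trace with the burst added to all three axes.
#' @export
plant_calibration_burst <- function(trace, t_burst_s, amplitude = 10,
                                    freq_hz = 1.5, width_s = 2) {
  if (t_burst_s < 60 || t_burst_s > 120) {
    stop("t_burst_s must lie in the 60-120 s calibration window, got ",
         t_burst_s)
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("a calibration burst was requested but amplitude is not positive; ",
         "refusing to emit a burst-free trace")
  }
  t_s <- trace$t_s
  sel <- abs(t_s - t_burst_s) <= width_s / 2
  if (!any(sel)) stop("burst window lies outside the trace")
  tt <- t_s[sel] - t_burst_s
  hann <- 0.5 * (1 + cos(2 * pi * tt / width_s))
  burst <- amplitude * hann * sin(2 * pi * freq_hz * tt)
  per_axis <- burst / sqrt(3)
  trace$x[sel] <- trace$x[sel] + per_axis
  trace$y[sel] <- trace$y[sel] + per_axis
  trace$z[sel] <- trace$z[sel] + per_axis
  attr(trace, "t_burst_s") <- t_burst_s
  trace
}

#' Simulate one dyad's two conversations
#'
#' Generates the four accelerometer traces (two participants x two
#' conversations) for one dyad, with interpersonal coupling drawn from
#' `coupling_map` according to each conversation's type and the dyad's task
#' condition, and a calibration burst planted 60-120 s into each trace.
#'
#' @param design A [study_design()].
#' @param coupling A [coupling_spec()] providing the baseline movement
#'   parameters; its gains are overridden per conversation by `coupling_map`.
#' @param dyad_id Integer dyad index into the design.
#' @param coupling_map Condition-to-gain map, see [default_coupling_map()].
#'
#' @return A list of class `dyad_recording` with elements `dyad`, `task`,
#'   and `conversations`: per conversation, traces `a` and `b`, the
#'   conversation type and number, and the planted burst times.
#' @export
simulate_dyad <- function(design, coupling = coupling_spec(), dyad_id = 1,
                          coupling_map = default_coupling_map()) {
  dur <- design$conversation_duration_s
  if (dur < 180) {
    stop("conversation_duration_s must be >= 180 s so the 60-120 s ",
         "calibration window plus usable conversation data fit; got ", dur)
  }
  fs <- design$sample_rate_hz
  coarse_hz <- 10
  task <- design$task[dyad_id]
  conv_types <- design$conversation_order[[dyad_id]]

  conversations <- lapply(seq_along(conv_types), function(ci) {
    ctype <- conv_types[ci]
    row <- coupling_map[coupling_map$conv_type == ctype &
                          coupling_map$task == task, ]
    if (nrow(row) != 1) stop("coupling_map has no entry for ", ctype, "/", task)
    spec <- coupling
    spec$inphase_gain <- row$inphase_gain
    spec$turntaking_gain <- row$turntaking_gain

    bouts <- simulate_bouts(round(dur * coarse_hz), spec)
    t_bursts <- stats::runif(2, 60, 120)
    traces <- lapply(1:2, function(i) {
      tr <- drive_to_trace(bouts[, i], spec, dur, fs, coarse_hz,
                           participant = c("a", "b")[i], conversation = ci)
      plant_calibration_burst(tr, t_bursts[i],
                              amplitude = spec$burst_amplitude)
    })
    list(a = traces[[1]], b = traces[[2]], conv_type = ctype,
         conv_num = ci, t_bursts = t_bursts)
  })
  structure(list(dyad = dyad_id, task = task, conversations = conversations),
            class = "dyad_recording")
}

#' Apply server-dropout censoring to a set of traces
#'
#' Each trace is independently censored at an exponentially distributed
#' disconnect time: data up to the disconnect are kept sample-for-sample
#' (a prefix, never an interior gap), everything after is lost.
#'
#' @param traces A list of [accel_trace()] objects (typically a dyad's four
#'   participant-conversation traces).
#' @param spec A [dropout_spec()].
#'
#' @return A list with `traces` (censored) and `included` (`TRUE` iff every
#'   trace retains at least `spec$min_keep_s` seconds).
#' @export
apply_dropout <- function(traces, spec = dropout_spec()) {
  censored <- lapply(traces, function(tr) {
    if (spec$hazard_per_s <= 0) return(tr)
    t_cut <- stats::rexp(1, rate = spec$hazard_per_s)
    if (t_cut >= max(tr$t_s)) return(tr)
    keep <- tr$t_s <= t_cut
    if (sum(keep) < 2) keep[1:2] <- TRUE
    out <- tr[keep, , drop = FALSE]
    attributes(out) <- c(attributes(out)[c("names", "row.names")],
                         attributes(tr)[setdiff(names(attributes(tr)),
                                                c("names", "row.names"))])
    out
  })
  included <- all(vapply(censored, duration_s, numeric(1)) >= spec$min_keep_s)
  list(traces = censored, included = included)
}

#' Simulate the 1 Hz red/blue stimulus stream
#'
#' One independently drawn screen color per second, blue with probability
#' 0.9 and red with probability 0.1 by default.
#'
#' @param duration_s Stream length in seconds (>= 1).
#' @param p_red Probability of a red screen at each draw.
#'
#' @return A character vector of `"blue"`/`"red"`, one element per second.
#' @export
simulate_stimulus_stream <- function(duration_s, p_red = 0.1) {
  stopifnot(duration_s >= 1)
  n <- floor(duration_s)
  c("blue", "red")[1L + stats::rbinom(n, 1L, p_red)]
}

#' Simulate a full dyadic study
#'
#' Generates every dyad in the design (seeded from `design$seed`), applies
#' dropout censoring, and assembles study-level metadata.
#'
#' @param design A [study_design()].
#' @param coupling Baseline [coupling_spec()].
#' @param coupling_map Condition-to-gain map.
#' @param dropout A [dropout_spec()]; the default applies no censoring.
#'
#' @return An object of class `dyad_study`: `design`, `dyads` (list of
#'   `dyad_recording`s, censored), and `metadata` (one row per
#'   dyad-conversation with inclusion flags).
#' @export
simulate_study <- function(design = study_design(),
                           coupling = coupling_spec(),
                           coupling_map = default_coupling_map(),
                           dropout = dropout_spec()) {
  if (!is.null(design$seed)) set.seed(design$seed)
  dyads <- vector("list", design$n_dyads)
  meta <- vector("list", design$n_dyads)
  for (d in seq_len(design$n_dyads)) {
    rec <- simulate_dyad(design, coupling, d, coupling_map)
    raw_traces <- unlist(lapply(rec$conversations, function(cv) list(cv$a, cv$b)),
                         recursive = FALSE)
    cens <- apply_dropout(raw_traces, dropout)
    k <- 1
    for (ci in seq_along(rec$conversations)) {
      rec$conversations[[ci]]$a <- cens$traces[[k]]
      rec$conversations[[ci]]$b <- cens$traces[[k + 1]]
      k <- k + 2
    }
    rec$included <- cens$included
    dyads[[d]] <- rec
    meta[[d]] <- data.frame(
      dyad = d,
      conversation = seq_along(rec$conversations),
      conv_type = vapply(rec$conversations, `[[`, "", "conv_type"),
      conv_order = seq_along(rec$conversations),
      task = rec$task,
      included = cens$included)
  }
  structure(list(design = design, dyads = dyads,
                 metadata = do.call(rbind, meta)),
            class = "dyad_study")
}

#' @export
print.dyad_study <- function(x, ...) {
  cat(sprintf("<dyad_study> %d dyads, %d included\n", x$design$n_dyads,
              sum(vapply(x$dyads, `[[`, logical(1), "included"))))
  invisible(x)
}

#' Two coupled AR(1) series
#'
#' Convenience generator for a pair of stationary AR(1) series whose
#' innovations share a common component, giving lag-0 cross-correlation
#' `coupling` between the innovation streams. Used as a minimal stand-in
#' for a coupled dyad when exercising the recurrence machinery directly.
#'
#' @param n Series length.
#' @param phi AR(1) coefficient.
#' @param coupling Innovation correlation in \[0, 1\].
#' @param sd Innovation standard deviation.
#'
#' @return A list with numeric vectors `a` and `b`.
#' @export
coupled_ar1 <- function(n, phi = 0.8, coupling = 0.6, sd = 1) {
  stopifnot(n >= 2, abs(phi) < 1, coupling >= 0, coupling <= 1)
  shared <- stats::rnorm(n)
  w <- sqrt(coupling)
  mix <- function() {
    e <- sd * (w * shared + sqrt(1 - coupling) * stats::rnorm(n))
    as.numeric(stats::filter(e, phi, method = "recursive"))
  }
  list(a = mix(), b = mix())
}
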