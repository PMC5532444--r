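#' Fourier phase-randomized surrogate
#'
#' Keeps the series' discrete Fourier amplitude spectrum (hence its power
#' spectrum and autocorrelation) while drawing new phases uniformly at
#' random, with conjugate symmetry enforced so the output is real. The DC
#' bin is untouched (the mean is preserved exactly) and, for even lengths,
#' the Nyquist bin is kept as-is (it must stay real).
#'
#' @param x Numeric series or [movement_series()] (length >= 4, finite).
#'
#' @return A numeric surrogate series of the same length.
#' @export
phase_randomize <- function(x) {
  if (is.data.frame(x)) x <- x$a
  if (any(!is.finite(x))) stop("input contains non-finite values")
  n <- length(x)
  if (n < 4) stop("need at least 4 samples to phase-randomize, got ", n)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  idx <- seq_len(half) + 1L                # positive frequencies, no DC/Nyquist
  phases <- stats::runif(half, 0, 2 * pi)
  X[idx] <- Mod(X[idx]) * exp(1i * phases)
  X[n + 2L - idx] <- Conj(X[idx])          # mirror bins
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Sample-wise shuffled surrogate
#'
#' A uniformly random permutation of the series' samples: the exact value
#' multiset (hence mean, variance, full marginal distribution) is
#' preserved while all temporal structure, including autocorrelation, is
#' destroyed.
#'
#' @param x Numeric series or [movement_series()] (length >= 2).
#'
#' @return A permuted numeric series.
#' @export
sample_shuffle <- function(x) {
  if (is.data.frame(x)) x <- x$a
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to shuffle, got ", n)
  x[sample.int(n)]
}

#' Surrogate ensemble for one series
#'
#' @param x Parent series.
#' @param method `"phase_randomization"` or `"sample_shuffle"`.
#' @param n_surrogates Ensemble size (default 10).
#'
#' @return A list of `n_surrogates` surrogate series.
#' @export
surrogate_ensemble <- function(x, method = c("phase_randomization",
                                             "sample_shuffle"),
                               n_surrogates = 10) {
  method <- match.arg(method)
  fn <- switch(method, phase_randomization = phase_randomize,
               sample_shuffle = sample_shuffle)
  lapply(seq_len(n_surrogates), function(i) fn(x))
}

#' Surrogate-baseline diagonal recurrence profiles
#'
#' For every conversation of a preprocessed study, generates `n_surrogates`
#' surrogate pairs (both participants randomized with independent draws,
#' which destroys cross-series alignment while preserving each margin's
#' autocorrelation under phase randomization) and pushes each pair through
#' the identical CRQA pathway using the parent conversation's stored delay,
#' dimension, and radius — no re-calibration, so surrogate overall RR may
#' legitimately differ from the 5% target.
#'
#' @param prepped A `prepped_study` from [preprocess_study()].
#' @param params_by_conv Data frame of per-conversation parameters with
#'   columns `dyad`, `conversation`, `delay`, `dimension`, `radius`
#'   (as written by [crqa_study()]).
#' @param method Surrogate method.
#' @param n_surrogates Ensemble size per conversation (default 10).
#' @param max_lag Profile half-width in samples.
#'
#' @return A long data frame of DRP rows: `dyad`, `conversation`,
#'   `conv_type`, `task`, `source = "surrogate"`, `surrogate_id`, `lag`,
#'   `rr`.
#' @export
build_baseline_drps <- function(prepped, params_by_conv,
                                method = c("phase_randomization",
                                           "sample_shuffle"),
                                n_surrogates = 10, max_lag = 50) {
  method <- match.arg(method)
  out <- vector("list", length(prepped$conversations) * n_surrogates)
  k <- 1L
  for (cv in prepped$conversations) {
    pr <- params_by_conv[params_by_conv$dyad == cv$dyad &
                           params_by_conv$conversation == cv$conversation, ]
    if (nrow(pr) != 1 || any(is.na(pr[c("delay", "dimension", "radius")]))) {
      stop("missing embedding parameters for dyad ", cv$dyad,
           " conversation ", cv$conversation,
           "; run crqa_study on the real data first")
    }
    fn <- switch(method, phase_randomization = phase_randomize,
                 sample_shuffle = sample_shuffle)
    for (s in seq_len(n_surrogates)) {
      # same pathway as the real data (z-score, embed with the parent's
      # delay/dimension, profile at the parent's radius) but streamed
      # per diagonal only: the surrogate's overall RR is not re-targeted
      A <- embed_series(as.numeric(scale(fn(cv$a))), pr$delay, pr$dimension)
      B <- embed_series(as.numeric(scale(fn(cv$b))), pr$delay, pr$dimension)
      drp <- drp_stream(A, B, pr$radius, max_lag)
      stopifnot(all(is.finite(drp$rr)))
      out[[k]] <- data.frame(
        dyad = cv$dyad, conversation = cv$conversation,
        conv_type = cv$conv_type, task = cv$task,
        source = "surrogate", surrogate_id = s,
        lag = drp$lag, rr = drp$rr)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
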