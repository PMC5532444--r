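# Binned mutual information between a series and its lagged copy.
ami_lagged <- function(x, lag, nbins = 16) {
  n <- length(x)
  u <- x[1:(n - lag)]
  v <- x[(1 + lag):n]
  cu <- cut(u, breaks = nbins, labels = FALSE)
  cv <- cut(v, breaks = nbins, labels = FALSE)
  joint <- table(cu, cv) / length(u)
  pu <- rowSums(joint)
  pv <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pu, pv)[nz]))
}

#' Embedding delay by average mutual information
#'
#' The delay is the first local minimum of the average mutual information
#' (AMI) over lags `1..max_delay`; if AMI has no local minimum, the lag of
#' the first autocorrelation zero-crossing is used; failing both,
#' `max_delay` is returned with a warning.
#'
#' @param x Numeric series or [movement_series()].
#' @param max_delay Largest lag considered, in samples. Capped at a tenth
#'   of the series length.
#' @param nbins Number of equal-width bins for the AMI histogram.
#'
#' @return Integer delay in samples.
#' @export
estimate_delay <- function(x, max_delay = 40, nbins = 16) {
  if (is.data.frame(x)) x <- x$a
  if (stats::sd(x) < 1e-12) {
    stop("cannot estimate a delay for a (near-)constant series")
  }
  max_delay <- max(1L, min(max_delay, floor(length(x) / 10)))
  if (max_delay == 1L) return(1L)
  ami <- vapply(seq_len(max_delay), function(k) ami_lagged(x, k, nbins),
                numeric(1))
  rising <- which(diff(ami) > 0)
  if (length(rising)) return(as.integer(rising[1]))
  ac <- stats::acf(x, lag.max = max_delay, plot = FALSE)$acf[-1]
  zc <- which(ac <= 0)
  if (length(zc)) return(as.integer(zc[1]))
  warning("no AMI minimum or autocorrelation zero-crossing up to lag ",
          max_delay, "; using max_delay")
  as.integer(max_delay)
}

#' Embedding dimension by false nearest neighbors
#'
#' Kennel's false-nearest-neighbor criterion: the dimension is the smallest
#' `m` at which fewer than `threshold` of the points' nearest neighbors in
#' `m` dimensions are "false", i.e. their separation grows by more than
#' `rtol` relative when the (m+1)-th coordinate is added. Reference points
#' whose nearest neighbor is farther than `sd(x)/atol` have no reliable
#' neighbor and are excluded from the fraction. Capped at `max_dim`.
#'
#' @param x Numeric series or [movement_series()].
#' @param delay Embedding delay in samples.
#' @param max_dim Largest dimension considered.
#' @param rtol,atol Kennel false-neighbor tolerances.
#' @param threshold FNN fraction below which a dimension is accepted.
#' @param max_points Cap on reference points (even stride subsample) for
#'   the neighbor search.
#'
#' @return Integer dimension.
#' @export
estimate_dimension <- function(x, delay, max_dim = 10, rtol = 10, atol = 2,
                               threshold = 0.1, max_points = 400) {
  if (is.data.frame(x)) x <- x$a
  if (stats::sd(x) < 1e-12) {
    stop("cannot estimate a dimension for a (near-)constant series")
  }
  sdx <- stats::sd(x)
  for (m in seq_len(max_dim)) {
    n_pts <- length(x) - m * delay          # valid for the (m+1)-dim check
    if (n_pts < 10) next                    # this m cannot be assessed
    E <- embed_series(x, delay, m)[seq_len(n_pts), , drop = FALSE]
    nxt <- x[seq_len(n_pts) + m * delay]
    ref <- unique(round(seq(1, n_pts, length.out = min(max_points, n_pts))))
    floor_d <- 1e-8 * sdx
    false_nn <- vapply(ref, function(i) {
      d2 <- colSums((t(E) - E[i, ])^2)
      d2[i] <- Inf
      # exclude temporally adjacent points so trivial neighbors don't count
      excl <- max(1, i - delay):min(n_pts, i + delay)
      d2[excl] <- Inf
      dmin <- min(d2)
      dm <- sqrt(dmin)
      if (dm > sdx / atol) return(NA)      # no reliable neighbor
      # all tied nearest neighbors considered: a point is false if any of
      # them separates when the next coordinate is added (exact duplicates
      # on periodic data make the single-neighbor ratio ill-defined)
      ties <- which(d2 <= dmin * (1 + 1e-9) + floor_d^2)
      gap <- max(abs(nxt[i] - nxt[ties]))
      gap / max(dm, floor_d) > rtol
    }, logical(1))
    frac <- if (all(is.na(false_nn))) 1 else mean(false_nn, na.rm = TRUE)
    if (frac < threshold) return(as.integer(m))
  }
  warning("false-nearest-neighbor fraction never fell below ", threshold,
          " up to dimension ", max_dim, "; using the cap")
  as.integer(max_dim)
}

#' Time-delay embedding
#'
#' Lifts a scalar series into `dimension`-dimensional points
#' `(s_i, s_{i+delay}, ..., s_{i+(m-1) delay})`.
#'
#' @param x Numeric series or [movement_series()].
#' @param delay Delay in samples (>= 1).
#' @param dimension Embedding dimension (>= 1).
#'
#' @return A numeric matrix with `length(x) - (dimension-1)*delay` rows.
#' @export
embed_series <- function(x, delay, dimension) {
  if (is.data.frame(x)) x <- x$a
  stopifnot(delay >= 1, dimension >= 1)
  n_pts <- length(x) - (dimension - 1) * delay
  if (n_pts < 1) {
    stop("series of length ", length(x), " too short to embed with delay ",
         delay, " and dimension ", dimension)
  }
  idx <- seq_len(n_pts)
  vapply(seq_len(dimension) - 1L,
         function(k) x[idx + k * delay],
         numeric(n_pts)) |> matrix(nrow = n_pts)
}

# All pairwise cross Euclidean distances, computed in row chunks of A to
# bound peak memory; returns the full vector (length nrow(A) * nrow(B)).
cross_distances <- function(A, B, chunk_elems = 5e6) {
  na <- nrow(A); nb <- nrow(B)
  out <- numeric(na * nb)
  rows_per_chunk <- max(1L, floor(chunk_elems / nb))
  pos <- 1L
  for (start in seq(1L, na, by = rows_per_chunk)) {
    end <- min(na, start + rows_per_chunk - 1L)
    d2 <- matrix(0, end - start + 1L, nb)
    for (k in seq_len(ncol(A))) {
      d2 <- d2 + outer(A[start:end, k], B[, k], "-")^2
    }
    nvals <- length(d2)
    out[pos:(pos + nvals - 1L)] <- sqrt(t(d2))
    pos <- pos + nvals
  }
  out
}

# Count of cross pairs within the radius, chunked; never materializes the
# recurrence matrix.
count_recurrent <- function(A, B, radius, chunk_elems = 5e6) {
  na <- nrow(A); nb <- nrow(B)
  r2 <- radius^2
  rows_per_chunk <- max(1L, floor(chunk_elems / nb))
  total <- 0
  for (start in seq(1L, na, by = rows_per_chunk)) {
    end <- min(na, start + rows_per_chunk - 1L)
    d2 <- matrix(0, end - start + 1L, nb)
    for (k in seq_len(ncol(A))) {
      d2 <- d2 + outer(A[start:end, k], B[, k], "-")^2
    }
    total <- total + sum(d2 <= r2)
  }
  total
}

#' Calibrate the recurrence radius to a target recurrence rate
#'
#' Sets the radius to the empirical `target_rr` quantile (linear
#' interpolation between order statistics) of all pairwise cross-distances
#' between the two embedded point sets, so the overall cross-recurrence
#' rate equals the target (5% by default).
#'
#' @param points_a,points_b Embedded point matrices (rows = points).
#' @param target_rr Target overall recurrence rate in (0, 1].
#'
#' @return A list with `radius`, `achieved_rr` (recounted at that radius)
#'   and `n_pairs`.
#' @export
calibrate_radius <- function(points_a, points_b, target_rr = 0.05) {
  if (!is.matrix(points_a)) points_a <- matrix(points_a, ncol = 1)
  if (!is.matrix(points_b)) points_b <- matrix(points_b, ncol = 1)
  if (target_rr <= 0 || target_rr > 1) {
    stop("target_rr must lie in (0, 1]; a zero recurrence rate has no ",
         "defining radius")
  }
  if (nrow(points_a) < 1 || nrow(points_b) < 1) stop("empty point set")
  d <- cross_distances(points_a, points_b)
  if (max(d) - min(d) < 1e-12) {
    stop("degenerate geometry: all cross-distances are identical, the ",
         "recurrence rate jumps from 0 to 1 and no radius attains ",
         target_rr)
  }
  radius <- stats::quantile(d, probs = target_rr, names = FALSE, type = 7)
  list(radius = radius,
       achieved_rr = mean(d <= radius),
       n_pairs = length(d))
}

#' Cross-recurrence matrix
#'
#' The binary matrix with entry (i, j) = 1 iff the Euclidean distance
#' between point i of A and point j of B is within the radius. Intended
#' for small inputs and oracle checks; the pipeline itself streams
#' per-diagonal counts and never builds this matrix.
#'
#' @param points_a,points_b Embedded point matrices.
#' @param radius Recurrence radius (> 0).
#'
#' @return A logical matrix (`nrow(points_a)` x `nrow(points_b)`).
#' @export
cross_recurrence <- function(points_a, points_b, radius) {
  if (!is.matrix(points_a)) points_a <- matrix(points_a, ncol = 1)
  if (!is.matrix(points_b)) points_b <- matrix(points_b, ncol = 1)
  stopifnot(radius > 0)
  na <- nrow(points_a); nb <- nrow(points_b)
  if (na * nb > 2.5e7) {
    stop("recurrence matrix of ", na, " x ", nb, " entries would be too ",
         "large; use the streaming profile instead")
  }
  d2 <- matrix(0, na, nb)
  for (k in seq_len(ncol(points_a))) {
    d2 <- d2 + outer(points_a[, k], points_b[, k], "-")^2
  }
  d2 <= radius^2
}

# Streaming diagonal recurrence profile: counts recurrent pairs (i, i+d)
# per lag d without materializing the matrix. Positive lag d means A at t
# is compared with B at t + d (A leading B).
drp_stream <- function(points_a, points_b, radius, max_lag) {
  na <- nrow(points_a); nb <- nrow(points_b)
  r2 <- radius^2
  lags <- -max_lag:max_lag
  rr <- numeric(length(lags))
  npt <- integer(length(lags))
  for (li in seq_along(lags)) {
    d <- lags[li]
    i0 <- max(1L, 1L - d)
    i1 <- min(na, nb - d)
    if (i1 < i0) stop("matrix too small for lag ", d)
    ii <- i0:i1
    d2 <- 0
    for (k in seq_len(ncol(points_a))) {
      d2 <- d2 + (points_a[ii, k] - points_b[ii + d, k])^2
    }
    npt[li] <- length(ii)
    rr[li] <- sum(d2 <= r2) / length(ii)
  }
  structure(data.frame(lag = lags, rr = rr, n_points = npt),
            class = c("drp", "data.frame"))
}

#' Diagonal recurrence profile of a recurrence matrix
#'
#' The recurrence rate along each diagonal of the cross-recurrence matrix
#' for lags `-max_lag..max_lag` (101 values for the default +/-50, the
#' +/-5 s window at 10 Hz). Positive lag means participant A at time t
#' leads participant B at t + lag.
#'
#' @param x A logical/binary recurrence matrix from [cross_recurrence()].
#' @param max_lag Maximum |lag| in samples (default 50).
#'
#' @return A data frame of class `drp` with columns `lag`, `rr`,
#'   `n_points`.
#' @export
diagonal_profile <- function(x, max_lag = 50) {
  stopifnot(is.matrix(x))
  if (nrow(x) < max_lag + 1 || ncol(x) < max_lag + 1) {
    stop("matrix (", nrow(x), " x ", ncol(x), ") too small for lags up to ",
         max_lag)
  }
  lags <- -max_lag:max_lag
  rr <- numeric(length(lags))
  npt <- integer(length(lags))
  for (li in seq_along(lags)) {
    d <- lags[li]
    i0 <- max(1L, 1L - d)
    i1 <- min(nrow(x), ncol(x) - d)
    ii <- i0:i1
    vals <- x[cbind(ii, ii + d)]
    npt[li] <- length(ii)
    rr[li] <- mean(vals)
  }
  structure(data.frame(lag = lags, rr = rr, n_points = npt),
            class = c("drp", "data.frame"))
}

#' Continuous cross-recurrence analysis of a series pair
#'
#' Full CRQA for one dyad-conversation: both series are z-scored, embedding
#' parameters are estimated per series by AMI (delay) and false nearest
#' neighbors (dimension) and shared as the pairwise maxima, the radius is
#' calibrated so the overall cross-recurrence rate is `target_rr` (5%), and
#' the diagonal recurrence profile is computed over `+/- max_lag` samples
#' by per-diagonal streaming.
#'
#' @param series_a,series_b Equal-length [movement_series()] (or numeric
#'   vectors) at the analysis rate.
#' @param delay,dimension,radius Optional fixed embedding parameters;
#'   estimated/calibrated when `NULL`. A supplied radius skips calibration
#'   (used for surrogate runs with the parent's parameters).
#' @param target_rr Target overall recurrence rate.
#' @param max_lag Profile half-width in samples.
#' @param rescale If `TRUE` (default) z-score each series before embedding
#'   so the radius is comparable across dyads.
#'
#' @return An object of class `crqa_result`: `rr` (overall), `drp`
#'   (101-row profile), and `params` (`delay`, `dimension`, `radius`,
#'   `calibrated_rr`).
#' @export
run_crqa <- function(series_a, series_b, delay = NULL, dimension = NULL,
                     radius = NULL, target_rr = 0.05, max_lag = 50,
                     rescale = TRUE) {
  a <- if (is.data.frame(series_a)) series_a$a else as.numeric(series_a)
  b <- if (is.data.frame(series_b)) series_b$a else as.numeric(series_b)
  if (length(a) != length(b)) {
    stop("series must have equal length (", length(a), " vs ", length(b),
         "); run trim_and_truncate first")
  }
  if (rescale) {
    a <- as.numeric(scale(a))
    b <- as.numeric(scale(b))
  }
  if (is.null(delay)) {
    delay <- max(estimate_delay(a), estimate_delay(b))
  }
  if (is.null(dimension)) {
    dimension <- max(estimate_dimension(a, delay),
                     estimate_dimension(b, delay))
  }
  A <- embed_series(a, delay, dimension)
  B <- embed_series(b, delay, dimension)
  calibrated_rr <- NA_real_
  if (is.null(radius)) {
    cal <- calibrate_radius(A, B, target_rr)
    radius <- cal$radius
    calibrated_rr <- cal$achieved_rr
    rr <- cal$achieved_rr
  } else {
    rr <- count_recurrent(A, B, radius) / (nrow(A) * nrow(B))
  }
  drp <- drp_stream(A, B, radius, max_lag)
  stopifnot(nrow(drp) == 2 * max_lag + 1)
  structure(list(rr = rr, drp = drp,
                 params = list(delay = delay, dimension = dimension,
                               radius = radius,
                               calibrated_rr = calibrated_rr),
                 n = length(a)),
            class = "crqa_result")
}

#' @export
print.crqa_result <- function(x, ...) {
  cat(sprintf(
    "<crqa_result> n=%d delay=%d dim=%d radius=%.4g | RR=%.4f, DRP %d lags (peak %.4f @ %+d)\n",
    x$n, x$params$delay, x$params$dimension, x$params$radius, x$rr,
    nrow(x$drp), max(x$drp$rr), x$drp$lag[which.max(x$drp$rr)]))
  invisible(x)
}

#' Plot a diagonal recurrence profile
#'
#' Minimal profile plot: recurrence rate against lag (samples), optionally
#' overlaying surrogate-baseline profiles as dashed lines.
#'
#' @param x A `drp` data frame or `crqa_result`.
#' @param baseline Optional list of baseline `drp`s drawn dashed.
#' @param ... Passed to [plot()].
#' @export
plot_drp <- function(x, baseline = NULL, ...) {
  drp <- if (inherits(x, "crqa_result")) x$drp else x
  ylim <- range(drp$rr, unlist(lapply(baseline, `[[`, "rr")))
  plot(drp$lag, drp$rr, type = "l", lwd = 2, ylim = ylim,
       xlab = "lag (samples)", ylab = "recurrence rate", ...)
  for (b in baseline) lines(b$lag, b$rr, lty = 2, col = "grey50")
  invisible(drp)
}
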