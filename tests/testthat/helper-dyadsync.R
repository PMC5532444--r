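# Brute-force oracles and small fixture builders shared across test files.

# Average mutual information by explicit per-cell accumulation, independent
# of the package's table-based implementation.
oracle_ami <- function(x, lag, nbins = 16) {
  n <- length(x)
  u <- x[1:(n - lag)]
  v <- x[(1 + lag):n]
  brk_u <- seq(min(u), max(u), length.out = nbins + 1)
  brk_v <- seq(min(v), max(v), length.out = nbins + 1)
  bu <- findInterval(u, brk_u, rightmost.closed = TRUE, all.inside = TRUE)
  bv <- findInterval(v, brk_v, rightmost.closed = TRUE, all.inside = TRUE)
  m <- length(u)
  mi <- 0
  for (i in seq_len(nbins)) {
    pi_ <- sum(bu == i) / m
    if (pi_ == 0) next
    for (j in seq_len(nbins)) {
      pij <- sum(bu == i & bv == j) / m
      if (pij > 0) mi <- mi + pij * log(pij / (pi_ * sum(bv == j) / m))
    }
  }
  mi
}

# Naive double-loop cross-recurrence: full binary matrix, overall RR, and
# per-diagonal profile.
oracle_crqa <- function(A, B, radius, max_lag) {
  na <- nrow(A)
  nb <- nrow(B)
  M <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      M[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2)) <= radius
    }
  }
  lags <- -max_lag:max_lag
  rr <- vapply(lags, function(d) {
    ii <- max(1, 1 - d):min(na, nb - d)
    mean(M[cbind(ii, ii + d)])
  }, numeric(1))
  list(matrix = M, rr_overall = mean(M), lags = lags, drp = rr)
}

# Low-rate, low-amplitude noise trace (cheap stand-in for a still
# participant) at an arbitrary sampling rate.
quiet_trace <- function(duration_s, fs = 5, noise = 0.01) {
  n <- round(duration_s * fs)
  t_s <- seq(0, by = 1 / fs, length.out = n)
  accel_trace(t_s, rnorm(n, 0, noise), rnorm(n, 0, noise),
              rnorm(n, 0, noise), sample_rate_hz = fs)
}

ms10 <- function(a, participant = "a", conversation = 1) {
  movement_series(seq(0, by = 0.1, length.out = length(a)), a,
                  participant = participant, conversation = conversation)
}

# Preprocessed-study object built directly from coupled AR(1) pairs at
# 10 Hz, skipping the accelerometer stage, for recurrence/surrogate/model
# tests that do not exercise preprocessing.
fake_prepped <- function(n_dyads = 2, n = 400, coupling = 0.5) {
  conversations <- list()
  tasks <- rep(c("dual-task", "noise"), length.out = n_dyads)
  for (d in seq_len(n_dyads)) {
    for (ci in 1:2) {
      pair <- coupled_ar1(n, phi = 0.9,
                          coupling = if (ci == 1) coupling else 0)
      conversations[[length(conversations) + 1]] <- list(
        dyad = d, conversation = ci,
        conv_type = c("affiliative", "argumentative")[ci],
        task = tasks[d],
        a = ms10(pair$a, "a", ci), b = ms10(pair$b, "b", ci),
        cutoff = NULL)
    }
  }
  structure(list(conversations = conversations, cutoffs = NULL,
                 included = rep(TRUE, n_dyads)),
            class = "prepped_study")
}

# Long-format DRP data frame with rr supplied per unit by `rr_fn(lags, c,
# k, dyad, source, sid)`; the backbone for growth-curve model tests.
fake_drp_df <- function(n_dyads = 21, rr_fn, n_surr = 0, lags = -50:50) {
  tasks <- rep(c("dual-task", "noise"), length.out = n_dyads)
  rows <- list()
  for (d in seq_len(n_dyads)) {
    for (ci in 1:2) {
      # counterbalanced order: odd dyads affiliative first, even reversed
      ctype <- if (d %% 2 == 1) {
        c("affiliative", "argumentative")[ci]
      } else {
        c("argumentative", "affiliative")[ci]
      }
      cc <- as.numeric(ctype == "argumentative")
      kk <- as.numeric(tasks[d] == "noise")
      sources <- c(list(list(src = "real", sid = NA_integer_)),
                   if (n_surr > 0) lapply(seq_len(n_surr), function(s) {
                     list(src = "surrogate", sid = s)
                   }))
      for (sc in sources) {
        rows[[length(rows) + 1]] <- data.frame(
          dyad = d, conversation = ci, conv_type = ctype, task = tasks[d],
          source = sc$src, surrogate_id = sc$sid, lag = lags,
          rr = rr_fn(lags, cc, kk, d, sc$src, sc$sid))
      }
    }
  }
  do.call(rbind, rows)
}

# One full end-to-end parameter-recovery replicate at the desk-scale
# Monte-Carlo conditions (21 dyads, 180-s conversations, fixed embedding).
power_replicate <- function(seed, n_dyads = 21, duration_s = 180) {
  des <- study_design(n_dyads = n_dyads,
                      conversation_duration_s = duration_s, seed = seed)
  st <- simulate_study(des)
  pp <- preprocess_study(st, min_keep_s = 150)
  real <- crqa_study(pp, delay = 5, dimension = 4)
  surr <- build_baseline_drps(pp, real$params)
  fit <- fit_full_model(assemble_gca_table(real$drps), standardized = TRUE,
                        slope_candidates = "c")
  cc <- fit$coefficients[fit$coefficients$term == "c", ]
  cf <- fit_baseline_contrast_models(
    assemble_gca_table(rbind(real$drps, surr)), standardized = TRUE,
    slope_candidates = character())$full
  dq <- cf$coefficients[cf$coefficients$term == "data:q", ]
  list(c_est = cc$estimate, c_p = cc$p, dq_t = dq$t, dq_p = dq$p)
}
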