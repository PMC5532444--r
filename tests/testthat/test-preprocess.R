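sine_trace <- function(freq_hz, fs = 250, duration_s = 20, amp = 1) {
  t_s <- seq(0, by = 1 / fs, length.out = round(duration_s * fs))
  accel_trace(t_s, amp * sin(2 * pi * freq_hz * t_s), 0 * t_s, 0 * t_s,
              sample_rate_hz = fs)
}

interior_amp <- function(v) {
  n <- length(v)
  max(abs(v[round(n / 4):round(3 * n / 4)]))
}

test_that("anti-alias filter passes the band, kills aliases, adds no phase", {
  tr1 <- antialias_filter(sine_trace(1))
  expect_lt(abs(interior_amp(tr1$x) - 1), 0.01)

  tr20 <- antialias_filter(sine_trace(20))
  # analytic two-pass Butterworth gain at 20 Hz with 5 Hz cutoff:
  # (1 + (20/5)^8)^-1 ~ 1.5e-5, far below the 1% bound asserted here
  expect_lt(interior_amp(tr20$x), 0.01)

  const <- quiet_trace(10, fs = 250, noise = 0)
  const$x <- rep(2.5, nrow(const))
  expect_equal(antialias_filter(const)$x, const$x, tolerance = 1e-6)

  # zero phase: peak cross-correlation of filtered vs raw at lag 0
  raw <- sine_trace(1)
  filt <- antialias_filter(raw)
  cc <- ccf(filt$x, raw$x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  short <- quiet_trace(0.04, fs = 250)
  expect_error(antialias_filter(short), "too short")
})

test_that("decimation keeps every k-th sample and rejects non-integer ratios", {
  tr <- sine_trace(1, fs = 250, duration_s = 60)
  dn <- downsample(tr, 10)
  expect_equal(nrow(dn), 600)
  expect_equal(attr(dn, "sample_rate_hz"), 10)
  expect_identical(dn$t_s, tr$t_s[seq(1, nrow(tr), by = 25)])

  tr243 <- sine_trace(1, fs = 243, duration_s = 10)
  expect_error(downsample(tr243, 10), "integer")
})

test_that("Euclidean acceleration is the per-sample 3-axis norm", {
  t_s <- seq(0, by = 0.1, length.out = 3)
  tr <- accel_trace(t_s, c(3, 0, 1), c(4, 0, 1), c(0, 0, 1),
                    sample_rate_hz = 10)
  ms <- euclidean_acceleration(tr)
  expect_equal(ms$a, c(5, 0, sqrt(3)))
  expect_true(all(ms$a >= 0))
})

test_that("smoothing preserves slow dynamics and reduces fast variance", {
  const <- ms10(rep(1.3, 200))
  expect_equal(smooth_series(const)$a, const$a, tolerance = 1e-6)

  alt <- ms10(rep(c(0, 1), 100))
  expect_lt(var(smooth_series(alt)$a), var(alt$a))

  t_s <- seq(0, by = 0.1, length.out = 400)
  slow <- ms10(sin(2 * pi * 0.5 * t_s))
  expect_lt(abs(interior_amp(smooth_series(slow)$a) - 1), 0.05)
})

test_that("jerk and jounce are central differences with documented edges", {
  t_s <- seq(0, by = 0.1, length.out = 100)
  ramp <- ms10(t_s)
  d <- derivatives(ramp)
  expect_equal(d$jerk$a[2:99], rep(1, 98), tolerance = 1e-9)
  expect_equal(d$jounce$a[3:98], rep(0, 98 - 2), tolerance = 1e-9)
  expect_equal(nrow(d$jerk), 100)

  quad <- ms10(t_s^2)
  expect_equal(derivatives(quad)$jounce$a[3:98], rep(2, 96),
               tolerance = 1e-9)

  # Gaussian bump on a flat series: |jounce| peaks at the bump center
  bump <- ms10(exp(-(t_s - 5)^2 / (2 * 0.5^2)))
  jn <- derivatives(bump)$jounce
  expect_lt(abs(jn$t_s[which.max(abs(jn$a))] - 5), 0.1 + 1e-9)

  expect_error(derivatives(ms10(c(1, 2))), "at least 3")
})

test_that("dyad cutoff is the later of the two jounce argmax times", {
  mkburst <- function(t_burst, seed) {
    set.seed(seed)
    plant_calibration_burst(quiet_trace(150, fs = 250, noise = 0.02),
                            t_burst) |>
      antialias_filter() |> downsample() |>
      euclidean_acceleration() |> smooth_series()
  }
  a <- mkburst(80, 1)
  b <- mkburst(95, 2)
  cut <- find_dyad_cutoff(a, b)
  expect_lt(abs(cut$jounce_a - 80), 1)
  expect_lt(abs(cut$jounce_b - 95), 1)
  expect_equal(cut$dyad, max(cut$jounce_a, cut$jounce_b))

  cut_same <- find_dyad_cutoff(a, a)
  expect_equal(cut_same$jounce_a, cut_same$jounce_b)
  expect_equal(cut_same$dyad, cut_same$jounce_a)

  set.seed(3)
  expect_error(find_dyad_cutoff(a, quiet_trace(100, fs = 10)), "window")
})

test_that("jerk- and jounce-based cutoffs agree across a simulated study", {
  st <- simulate_study(study_design(n_dyads = 8,
                                    conversation_duration_s = 200,
                                    seed = 77))
  pp <- preprocess_study(st, min_keep_s = 150)
  jerk <- unlist(lapply(pp$conversations,
                        function(cv) c(cv$cutoff$jerk_a, cv$cutoff$jerk_b)))
  jounce <- unlist(lapply(pp$conversations,
                          function(cv) c(cv$cutoff$jounce_a,
                                         cv$cutoff$jounce_b)))
  expect_gt(cor(jerk, jounce), 0.5)
})

test_that("trim and truncate aligns the pair at the cutoff", {
  a <- ms10(rnorm(4800 + 700))   # covers t >= 70 s: 4800 samples left
  b <- ms10(rnorm(4500 + 700))
  out <- trim_and_truncate(a, b, cutoff_s = 70)
  expect_equal(nrow(out$a), nrow(out$b))
  expect_equal(nrow(out$a), 4500)
  expect_gte(min(out$a$t_s), 70)
  expect_true(attr(out$a, "trimmed"))

  same <- trim_and_truncate(a, a, cutoff_s = 0)
  expect_equal(nrow(same$a), nrow(a))

  expect_error(trim_and_truncate(a, b, cutoff_s = 1e5), "no samples")
})

test_that("inclusion requires 4.5 min in all four traces, inclusively", {
  set.seed(4)
  mkstudy <- function(durs) {
    conv <- function(da, db, ci) list(a = quiet_trace(da, 5),
                                      b = quiet_trace(db, 5),
                                      conv_type = "affiliative",
                                      conv_num = ci)
    rec <- structure(list(dyad = 1, task = "noise",
                          conversations = list(conv(durs[1], durs[2], 1),
                                               conv(durs[3], durs[4], 2))),
                     class = "dyad_recording")
    structure(list(dyads = list(rec)), class = "dyad_study")
  }
  expect_true(inclusion_filter(mkstudy(rep(480, 4))))
  # participant A recorded only 3 min of conversation 1: dyad excluded
  expect_false(inclusion_filter(mkstudy(c(180, 480, 480, 480))))
  expect_true(all(inclusion_filter(mkstudy(rep(270, 4)))))
})
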