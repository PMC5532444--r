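test_that("time-delay embedding produces lagged coordinate points", {
  E <- embed_series(c(1, 2, 3, 4), delay = 1, dimension = 2)
  expect_equal(E, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(embed_series(c(5, 6, 7), 3, 1), matrix(c(5, 6, 7)))
  expect_equal(nrow(embed_series(c(1, 2, 3, 4), 2, 2)), 2)
  expect_error(embed_series(c(1, 2, 3), 2, 3), "too short")
})

test_that("delay estimation finds the AMI minimum with sane fallbacks", {
  set.seed(42)
  wn <- rnorm(2000)
  expect_lte(estimate_delay(wn), 3)   # AMI of white noise is minimal at once

  x <- sin(2 * pi * (1:1000) / 40)
  d <- estimate_delay(x)
  expect_gte(d, 5)                    # near the quarter period (10)
  expect_lte(d, 15)
  # agrees with an independently coded AMI curve's first rising point
  ami <- vapply(1:20, function(k) oracle_ami(x, k), numeric(1))
  d_oracle <- which(diff(ami) > 0)[1]
  expect_lt(abs(d - d_oracle), 5)

  expect_error(estimate_delay(rep(1, 500)), "constant")
})

test_that("false-nearest-neighbor dimension settles on simple geometries", {
  x <- sin(2 * pi * (1:1000) / 40)
  expect_equal(estimate_dimension(x, delay = 10), 2)
  expect_equal(estimate_dimension(x, delay = 6), 2)

  set.seed(43)
  wn <- rnorm(1500)
  m <- suppressWarnings(estimate_dimension(wn, delay = 1))
  expect_gte(m, 3)                    # noise never looks low-dimensional

  # candidate dimensions the series is too short to assess are skipped
  short <- sin(2 * pi * (1:80) / 16) + rnorm(80, 0, 0.01)
  expect_no_error(suppressWarnings(estimate_dimension(short, delay = 4)))
  expect_error(estimate_dimension(rep(2, 100), 1), "constant")
})

test_that("radius calibration hits the target recurrence rate", {
  set.seed(44)
  a <- matrix(rnorm(500), ncol = 1)
  b <- matrix(rnorm(500), ncol = 1)
  cal <- calibrate_radius(a, b, 0.05)
  expect_gte(cal$achieved_rr, 0.045)
  expect_lte(cal$achieved_rr, 0.055)

  # oracle: brute-force sort of all n^2 distances, 5th percentile, recount
  d_all <- sqrt(as.vector(outer(a[, 1], b[, 1], "-")^2))
  expect_equal(cal$radius, quantile(d_all, 0.05, names = FALSE),
               tolerance = 1e-12)
  expect_equal(cal$achieved_rr, mean(d_all <= cal$radius), tolerance = 0)

  cal1 <- calibrate_radius(a, b, 1)
  expect_gte(cal1$radius, max(d_all))
  expect_equal(cal1$achieved_rr, 1)

  expect_error(calibrate_radius(a, b, 0), "target_rr")
  same <- matrix(rep(1, 10), ncol = 1)
  expect_error(calibrate_radius(same, same, 0.05), "degenerate")
})

test_that("cross-recurrence matrix matches the double-loop definition", {
  set.seed(45)
  A <- matrix(rnorm(60), ncol = 2)
  B <- matrix(rnorm(60), ncol = 2)
  M <- cross_recurrence(A, B, 0.8)
  or <- oracle_crqa(A, B, 0.8, 5)
  expect_identical(unname(M), or$matrix)
  expect_equal(mean(M), or$rr_overall)

  expect_true(all(diag(cross_recurrence(A, A, 1e-9))))
  expect_true(all(cross_recurrence(A, B, 100)))
})

test_that("diagonal profile has the right geometry and symmetry", {
  ones <- matrix(TRUE, 60, 60)
  drp <- diagonal_profile(ones, max_lag = 50)
  expect_equal(nrow(drp), 101)
  expect_equal(drp$lag, -50:50)
  expect_true(all(drp$rr == 1))

  set.seed(46)
  M <- matrix(runif(80 * 80) < 0.1, 80, 80)
  d_ab <- diagonal_profile(M, 20)
  d_ba <- diagonal_profile(t(M), 20)
  expect_equal(d_ab$rr, rev(d_ba$rr))

  expect_error(diagonal_profile(matrix(TRUE, 10, 10), 50), "too small")
})

test_that("streaming CRQA equals the brute-force oracle exactly", {
  set.seed(47)
  cases <- list(list(n = 120, delay = 2, dim = 3),
                list(n = 200, delay = 1, dim = 2),
                list(n = 150, delay = 4, dim = 1))
  for (cs in cases) {
    a <- as.numeric(scale(cumsum(rnorm(cs$n))))
    b <- as.numeric(scale(cumsum(rnorm(cs$n))))
    res <- run_crqa(a, b, delay = cs$delay, dimension = cs$dim,
                    target_rr = 0.05, max_lag = 10, rescale = FALSE)
    A <- embed_series(a, cs$delay, cs$dim)
    B <- embed_series(b, cs$delay, cs$dim)
    or <- oracle_crqa(A, B, res$params$radius, 10)
    expect_equal(res$drp$rr, or$drp, tolerance = 0)
    expect_equal(res$rr, or$rr_overall, tolerance = 1e-12)
  }
})

test_that("recurrence rate is nondecreasing in the radius", {
  set.seed(48)
  a <- as.numeric(scale(cumsum(rnorm(150))))
  b <- as.numeric(scale(cumsum(rnorm(150))))
  A <- embed_series(a, 2, 2)
  B <- embed_series(b, 2, 2)
  rrs <- vapply(seq(0.05, 3, length.out = 12),
                function(r) mean(cross_recurrence(A, B, r)), numeric(1))
  expect_true(all(diff(rrs) >= 0))
})

test_that("a pure shift shows up at the signed lag of the leader", {
  set.seed(49)
  x <- as.numeric(scale(filter(rnorm(600), 0.95, method = "recursive")))
  a <- x[11:600]           # A(t) = x(t + 10)
  b <- x[1:590]            # B(t) = x(t); B(t+10) = A(t): A leads B
  res <- run_crqa(a, b, delay = 1, dimension = 1, target_rr = 0.05)
  expect_equal(res$drp$lag[which.max(res$drp$rr)], 10)

  rev_res <- run_crqa(b, a, delay = 1, dimension = 1, target_rr = 0.05)
  expect_equal(rev_res$drp$lag[which.max(rev_res$drp$rr)], -10)
  # full lag-reversal symmetry at a shared radius
  r2 <- run_crqa(b, a, delay = 1, dimension = 1,
                 radius = res$params$radius)
  expect_equal(r2$drp$rr, rev(res$drp$rr), tolerance = 1e-12)

  same <- run_crqa(x, x, delay = 1, dimension = 1, radius = 1e-9)
  expect_equal(same$drp$rr[same$drp$lag == 0], 1)

  expect_error(run_crqa(a, x), "equal length")
})
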