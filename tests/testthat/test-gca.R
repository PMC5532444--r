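test_that("orthogonal lag polynomials are orthonormal and symmetric", {
  p <- orthogonal_lag_polynomials()
  expect_equal(nrow(p), 101)
  expect_lt(abs(sum(p$l * p$q)), 1e-12)
  expect_lt(abs(sum(p$l)), 1e-12)
  expect_lt(abs(sum(p$q)), 1e-12)
  expect_equal(sum(p$l^2), 1)
  expect_equal(sum(p$q^2), 1)
  # l odd, q even in lag
  expect_equal(p$l, -rev(p$l))
  expect_equal(p$q, rev(p$q))
  # a pure parabola projects only onto q
  rr <- p$lag^2
  expect_lt(abs(sum(rr * p$l)), 1e-9)
  expect_gt(sum(rr * p$q), 0)
  expect_error(orthogonal_lag_polynomials(c(0, 1)), "3 distinct")
})

test_that("table assembly yields the factorial row counts and codes", {
  set.seed(61)
  f <- function(lags, c, k, dyad, source, sid) 0.05 + rnorm(101, 0, 0.001)
  df <- fake_drp_df(21, f)
  tab <- assemble_gca_table(df)
  expect_equal(nrow(tab), 21 * 2 * 101)      # 4242 real rows
  expect_setequal(unique(tab$c), c(0, 1))
  expect_setequal(unique(tab$k), c(0, 1))
  expect_null(tab$data)

  df2 <- fake_drp_df(21, f, n_surr = 10)
  tab2 <- assemble_gca_table(df2)
  expect_equal(sum(tab2$data == -0.5), 21 * 2 * 101 * 10)  # 42420 baseline
  expect_setequal(unique(tab2$data), c(-0.5, 0.5))

  dup <- rbind(df, df[1, ])
  expect_error(assemble_gca_table(dup), "duplicate lag")
  expect_error(assemble_gca_table(df[-1, ]), "does not cover")
})

test_that("the full model recovers planted fixed effects with 16 terms", {
  set.seed(62)
  p <- orthogonal_lag_polynomials()
  dyad_int <- rnorm(21, 0, 0.004)
  f <- function(lags, c, k, dyad, source, sid) {
    0.06 - 0.02 * c - 0.08 * p$q + 0.03 * c * p$q + dyad_int[dyad] +
      rnorm(101, 0, 0.004)
  }
  tab <- assemble_gca_table(fake_drp_df(21, f))
  fit <- fit_full_model(tab, slope_candidates = "c")
  expect_s3_class(fit, "gca_fit")
  expect_equal(nrow(fit$coefficients), 16)
  cc <- fit$coefficients[fit$coefficients$term == "c", ]
  expect_lt(cc$estimate, 0)
  expect_lt(cc$p, 0.05)
  expect_equal(abs(cc$estimate), 0.02, tolerance = 0.3)
  qq <- fit$coefficients[fit$coefficients$term == "q", ]
  expect_lt(qq$estimate, 0)

  # a pure-noise outcome leaves the lag structure non-significant
  set.seed(63)
  f0 <- function(lags, c, k, dyad, source, sid) rnorm(101, 0.05, 0.01)
  fit0 <- fit_full_model(assemble_gca_table(fake_drp_df(12, f0)),
                         slope_candidates = character())
  for (term in c("l", "q", "c:q")) {
    expect_gt(fit0$coefficients$p[fit0$coefficients$term == term], 1e-3)
  }
})

test_that("standardized and unstandardized fits agree in sign and t", {
  set.seed(64)
  p <- orthogonal_lag_polynomials()
  dyad_int <- rnorm(21, 0, 0.004)
  f <- function(lags, c, k, dyad, source, sid) {
    0.06 - 0.02 * c - 0.05 * p$q + dyad_int[dyad] + rnorm(101, 0, 0.004)
  }
  tab <- assemble_gca_table(fake_drp_df(21, f))
  # fixed random structure so both fits share the same model space
  fu <- fit_full_model(tab, standardized = FALSE,
                       slope_candidates = character())
  fs <- fit_full_model(tab, standardized = TRUE,
                       slope_candidates = character())
  m <- merge(fu$coefficients, fs$coefficients, by = "term")
  # predictors are scaled without centering, so every non-intercept t is
  # invariant (the intercept reflects the standardized outcome's centering)
  m <- m[m$term != "(Intercept)", ]
  expect_equal(m$t.x, m$t.y, tolerance = 1e-3)
  expect_true(all(sign(m$estimate.x) == sign(m$estimate.y)))
})

test_that("backward selection drops unsupported slopes and keeps real ones", {
  set.seed(65)
  dyad_int <- rnorm(21, 0, 0.005)
  f_flat <- function(lags, c, k, dyad, source, sid) {
    0.05 + dyad_int[dyad] + rnorm(101, 0, 0.004)
  }
  tab <- assemble_gca_table(fake_drp_df(21, f_flat))
  sel <- backward_select_random_slopes("c * k * l * q", tab,
                                       slope_candidates = c("c", "l", "q"))
  expect_lt(length(sel$slopes), 3)       # terminates at/near intercepts-only
  expect_true(any(sel$attempts$converged))
  expect_gte(nrow(sel$attempts), 1)

  # identical data give an identical attempt log
  sel2 <- backward_select_random_slopes("c * k * l * q", tab,
                                        slope_candidates = c("c", "l", "q"))
  expect_identical(sel$attempts, sel2$attempts)

  set.seed(66)
  dyad_slope <- rnorm(21, 0, 0.03)
  conv_slope <- c(-0.02, 0.02)   # both groupings carry real c-slope variance
  f_slope <- function(lags, c, k, dyad, source, sid) {
    ci <- if (dyad %% 2 == 1) c + 1 else 2 - c   # conversation number
    0.05 + dyad_int[dyad] + (dyad_slope[dyad] + conv_slope[ci]) * c +
      rnorm(101, 0, 0.003)
  }
  tab2 <- assemble_gca_table(fake_drp_df(21, f_slope))
  sel3 <- backward_select_random_slopes("c * k * l * q", tab2,
                                        slope_candidates = "c")
  expect_true("c" %in% sel3$slopes)
})

test_that("post-hoc models split by conversation with the right structure", {
  set.seed(67)
  p <- orthogonal_lag_polynomials()
  dyad_int <- rnorm(21, 0, 0.004)
  # affiliative curvature negative (inverted U), argumentative positive (U)
  f <- function(lags, c, k, dyad, source, sid) {
    0.05 + (-0.08 + 0.2 * c) * p$q + dyad_int[dyad] + rnorm(101, 0, 0.003)
  }
  tab <- assemble_gca_table(fake_drp_df(21, f))
  ph <- fit_posthoc_models(tab, slope_candidates = "q")
  expect_named(ph, c("affiliative", "argumentative"))
  expect_equal(nrow(ph$affiliative$coefficients), 8)
  q_aff <- ph$affiliative$coefficients
  q_arg <- ph$argumentative$coefficients
  expect_lt(q_aff$estimate[q_aff$term == "q"], 0)
  expect_gt(q_arg$estimate[q_arg$term == "q"], 0)
  expect_lt(q_arg$p[q_arg$term == "q"], 0.05)

  # single task level collapses to the 4-term lag-only model
  df1 <- fake_drp_df(10, f)
  df1$task <- "dual-task"
  ph1 <- fit_posthoc_models(assemble_gca_table(df1),
                            slope_candidates = character())
  expect_equal(nrow(ph1$affiliative$coefficients), 4)
})

test_that("baseline-contrast models require both sources and find data x q", {
  set.seed(68)
  p <- orthogonal_lag_polynomials()
  dyad_int <- rnorm(12, 0, 0.004)
  f <- function(lags, c, k, dyad, source, sid) {
    real <- as.numeric(source == "real")
    0.05 - 0.08 * real * p$q + dyad_int[dyad] + rnorm(101, 0, 0.004)
  }
  tab <- assemble_gca_table(fake_drp_df(12, f, n_surr = 4))
  cf <- fit_baseline_contrast_models(tab, slope_candidates = character())
  expect_equal(nrow(cf$full$coefficients), 32)
  dq <- cf$full$coefficients[cf$full$coefficients$term == "data:q", ]
  expect_lt(dq$estimate, 0)
  expect_lt(dq$p, 0.05)

  surr_only <- fake_drp_df(12, f, n_surr = 2)
  surr_only <- surr_only[surr_only$source == "surrogate", ]
  expect_error(
    fit_baseline_contrast_models(assemble_gca_table(surr_only)),
    "both real and surrogate")
})
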