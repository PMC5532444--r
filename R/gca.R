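#' First- and second-order orthogonal lag polynomials
#'
#' Orthonormal linear (`l`) and quadratic (`q`) polynomial codes over the
#' lag window, from Gram-Schmidt orthogonalization of (1, lag, lag^2): the
#' columns are mutually orthogonal, orthogonal to the constant, and have
#' unit norm. Over a symmetric window `l` is odd in lag
#' (leading/following asymmetry) and `q` is even (synchrony vs.
#' turn-taking curvature).
#'
#' @param lags Integer vector of lags (default `-50:50`); at least 3
#'   distinct values.
#'
#' @return A data frame with columns `lag`, `l`, `q`.
#' @export
orthogonal_lag_polynomials <- function(lags = -50:50) {
  if (length(unique(lags)) < 3) {
    stop("need at least 3 distinct lags for quadratic orthogonal polynomials")
  }
  P <- stats::poly(lags, degree = 2)
  data.frame(lag = lags, l = P[, 1], q = P[, 2])
}

#' Assemble the growth-curve modelling table
#'
#' Joins long-format DRP rows with condition codes and orthogonal lag
#' polynomial terms: `c` (conversation; affiliative 0, argumentative 1),
#' `k` (task; dual-task 0, noise 1), `l` and `q` (orthonormal lag terms).
#' When both real and surrogate rows are present a `data` contrast code is
#' added (real +0.5, surrogate -0.5). Every dyad-conversation-source unit
#' must contribute each lag exactly once.
#'
#' @param drp_df Long DRP data frame with columns `dyad`, `conversation`,
#'   `conv_type`, `task`, `lag`, `rr` and optionally `source`,
#'   `surrogate_id`.
#'
#' @return A data frame ready for the model fitters, with `dyad` and
#'   `conv_num` as factors.
#' @export
assemble_gca_table <- function(drp_df) {
  if (is.null(drp_df$source)) drp_df$source <- "real"
  if (is.null(drp_df$surrogate_id)) drp_df$surrogate_id <- NA_integer_
  lags <- sort(unique(drp_df$lag))
  unit <- interaction(drp_df$dyad, drp_df$conversation, drp_df$source,
                      ifelse(is.na(drp_df$surrogate_id), 0,
                             drp_df$surrogate_id), drop = TRUE)
  for (u in levels(unit)) {
    ul <- drp_df$lag[unit == u]
    if (anyDuplicated(ul)) {
      stop("duplicate lag within unit ", u)
    }
    if (length(ul) != length(lags) || !setequal(ul, lags)) {
      stop("unit ", u, " does not cover the full lag window (",
           length(ul), " of ", length(lags), " lags)")
    }
  }
  poly_df <- orthogonal_lag_polynomials(lags)
  stopifnot(abs(sum(poly_df$l * poly_df$q)) < 1e-10,
            abs(sum(poly_df$l^2) - 1) < 1e-8,
            abs(sum(poly_df$q^2) - 1) < 1e-8)
  out <- merge(drp_df, poly_df, by = "lag", sort = FALSE)
  out$c <- as.numeric(out$conv_type == "argumentative")
  out$k <- as.numeric(out$task == "noise")
  if (length(unique(out$source)) > 1) {
    out$data <- ifelse(out$source == "real", 0.5, -0.5)
  }
  out$dyad <- factor(out$dyad)
  out$conv_num <- factor(out$conversation)
  out[order(out$dyad, out$conversation, out$source, out$surrogate_id,
            out$lag), ]
}

# --- model fitting machinery -----------------------------------------------

# A slope label like "k:c:l" names the product of those columns; the
# product is stored under the concatenated name ("kcl") so it can appear
# in a random-effects bar term.
slope_column <- function(label) gsub(":", "", label, fixed = TRUE)

add_slope_columns <- function(table, labels) {
  for (lb in labels) {
    parts <- strsplit(lb, ":", fixed = TRUE)[[1]]
    col <- slope_column(lb)
    if (!col %in% names(table)) {
      table[[col]] <- Reduce(`*`, table[parts])
    }
  }
  table
}

re_term <- function(slopes, grouping) {
  if (length(slopes) == 0) return(sprintf("(1 | %s)", grouping))
  sprintf("(1 + %s | %s)",
          paste(vapply(slopes, slope_column, ""), collapse = " + "),
          grouping)
}

# Fit an lmer model, capturing convergence/singularity diagnostics.
# Fits that trip the convergence checks are retried once with bobyqa,
# which is markedly more robust when a variance sits on the zero boundary.
fit_lmer_checked <- function(formula_str, table) {
  fit_once <- function(ctrl) {
    warns <- character()
    fit <- withCallingHandlers(
      tryCatch(
        suppressMessages(
          lme4::lmer(stats::as.formula(formula_str), data = table,
                     REML = TRUE, control = ctrl)),
        error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warns = warns)
  }
  is_conv_warn <- function(w) {
    any(grepl("converge|Hessian|gradient|unable", w, ignore.case = TRUE))
  }
  res <- fit_once(lme4::lmerControl())
  conv_bad <- !inherits(res$fit, "error") && is_conv_warn(res$warns)
  if (conv_bad) {
    res2 <- fit_once(lme4::lmerControl(optimizer = "bobyqa",
                                       optCtrl = list(maxfun = 1e5)))
    if (!inherits(res2$fit, "error")) {
      if (!is_conv_warn(res2$warns)) {
        res <- res2
        conv_bad <- FALSE
      } else if (!inherits(res$fit, "error")) {
        # lme4's gradient/Hessian checks are known to raise false alarms;
        # when two independent optimizers land on the same solution the
        # fit is accepted as converged (the allFit heuristic)
        f1 <- lme4::fixef(res$fit)
        f2 <- lme4::fixef(res2$fit)
        agree <- max(abs(f1 - f2)) < 1e-4 * max(1, max(abs(f1))) &&
          abs(lme4::REMLcrit(res$fit) - lme4::REMLcrit(res2$fit)) < 1e-3
        if (agree) {
          res <- res2
          conv_bad <- FALSE
        }
      }
    }
  }
  if (inherits(res$fit, "error")) {
    return(list(fit = NULL, ok = FALSE, why = conditionMessage(res$fit)))
  }
  singular <- lme4::isSingular(res$fit, tol = 1e-4)
  ok <- !conv_bad && !singular
  why <- if (conv_bad) paste(res$warns, collapse = "; ")
         else if (singular) "singular fit (a variance component is ~0)"
         else ""
  list(fit = res$fit, ok = ok, why = why)
}

# Estimated variance of each slope's random effect, summed over groupings;
# used to pick the next slope to drop.
slope_variances <- function(fit, slopes, groupings) {
  vc <- lme4::VarCorr(fit)
  vapply(slopes, function(lb) {
    col <- slope_column(lb)
    tot <- 0
    for (g in groupings) {
      for (nm in names(vc)) {
        if (startsWith(nm, g)) {
          v <- diag(vc[[nm]])
          if (col %in% names(v)) tot <- tot + v[[col]]
        }
      }
    }
    tot
  }, numeric(1))
}

#' Backward selection of the random-slope structure
#'
#' Starts from the maximal candidate slope set (applied identically to both
#' grouping factors, dyad and conversation number) and removes one slope at
#' a time until the model converges without a singular fit: slopes of the
#' highest interaction order are dropped first, and within an order the
#' slope with the smallest estimated random-effect variance (summed over
#' groupings) goes first. Every attempt is logged.
#'
#' @param fixed_rhs Right-hand side of the fixed-effects formula, e.g.
#'   `"c * k * l * q"`.
#' @param table A table from [assemble_gca_table()].
#' @param slope_candidates Character vector of slope labels (columns or
#'   `:`-interactions of columns), e.g. `c("c", "l", "q", "k:c:l")`.
#' @param groupings Grouping factor names (default dyad and conversation
#'   number).
#'
#' @return A list: `fit` (lmerMod), `slopes` (retained labels),
#'   `attempts` (data frame log of every formula tried and why it was
#'   rejected).
#' @export
backward_select_random_slopes <- function(fixed_rhs, table,
                                          slope_candidates = c("c", "l", "q",
                                                               "k:c:l"),
                                          groupings = c("dyad", "conv_num")) {
  table <- add_slope_columns(table, slope_candidates)
  # recurrence rates live on a small numeric scale that trips lme4's
  # convergence checks; fit on the centered/scaled outcome and let the
  # caller map coefficients back (t-values and p-values are invariant)
  out_center <- mean(table$rr)
  out_scale <- stats::sd(table$rr)
  if (!is.finite(out_scale) || out_scale <= 0) {
    stop("outcome rr has no variance; nothing to model")
  }
  table$rr <- (table$rr - out_center) / out_scale
  current <- slope_candidates
  attempts <- list()
  last_fit <- NULL
  repeat {
    fstr <- paste("rr ~", fixed_rhs, "+",
                  paste(vapply(groupings, function(g) re_term(current, g), ""),
                        collapse = " + "))
    res <- fit_lmer_checked(fstr, table)
    attempts[[length(attempts) + 1]] <- data.frame(
      formula = fstr, converged = res$ok,
      note = if (res$ok) "accepted" else res$why)
    if (res$ok) {
      return(list(fit = res$fit, slopes = current,
                  attempts = do.call(rbind, attempts),
                  outcome_center = out_center, outcome_scale = out_scale))
    }
    if (length(current) == 0) {
      # a singular intercepts-only fit (a grouping variance on the zero
      # boundary) is accepted as the terminal model; only optimizer
      # failure is a hard error at this point
      singular_only <- !is.null(res$fit) &&
        !grepl("converge|Hessian|gradient|unable", res$why,
               ignore.case = TRUE)
      if (singular_only) {
        attempts[[length(attempts)]]$note <-
          "accepted (singular random-intercept variance)"
        attempts[[length(attempts)]]$converged <- TRUE
        return(list(fit = res$fit, slopes = character(),
                    attempts = do.call(rbind, attempts),
                    outcome_center = out_center, outcome_scale = out_scale))
      }
      stop("even the random-intercepts-only model failed: ", res$why,
           "\nAttempt log:\n",
           paste(vapply(attempts, function(a) a$formula, ""), collapse = "\n"))
    }
    if (!is.null(res$fit)) last_fit <- res$fit
    ord <- vapply(strsplit(current, ":", fixed = TRUE), length, integer(1))
    cand <- current[ord == max(ord)]
    drop <- if (!is.null(last_fit)) {
      v <- slope_variances(last_fit, cand, groupings)
      cand[which.min(v)]
    } else {
      cand[length(cand)]
    }
    current <- setdiff(current, drop)
  }
}

# Scale-only standardization: the outcome is centered and scaled, the
# predictors are scaled by their SD but not centered, so dummy codes keep
# their zero reference level, interaction columns stay products of their
# components, and every coefficient's t-value is invariant to the
# standardization.
standardize_gca <- function(table, predictors) {
  table$rr <- as.numeric(scale(table$rr))
  for (p in predictors) {
    s <- stats::sd(table[[p]])
    if (s > 0) table[[p]] <- table[[p]] / s
  }
  table
}

coef_table <- function(fit, model_name) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  t <- est / se
  data.frame(model = model_name, term = names(est), estimate = unname(est),
             se = unname(se), t = unname(t),
             p = 2 * stats::pnorm(-abs(t)), row.names = NULL)
}

new_gca_fit <- function(sel, model_name, standardized, n_fixed_expected) {
  ct <- coef_table(sel$fit, model_name)
  # undo the internal outcome scaling used for numerical stability
  ct$estimate <- ct$estimate * sel$outcome_scale
  ct$se <- ct$se * sel$outcome_scale
  ct$estimate[ct$term == "(Intercept)"] <-
    ct$estimate[ct$term == "(Intercept)"] + sel$outcome_center
  if (nrow(ct) != n_fixed_expected) {
    stop("expected ", n_fixed_expected, " fixed-effect terms in ",
         model_name, ", got ", nrow(ct))
  }
  structure(list(model = sel$fit, coefficients = ct,
                 slopes = sel$slopes, attempts = sel$attempts,
                 standardized = standardized),
            class = "gca_fit")
}

#' @export
print.gca_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<gca_fit>%s %d fixed effects; random slopes: %s\n",
              if (x$standardized) " standardized;" else "",
              nrow(x$coefficients),
              if (length(x$slopes)) paste(x$slopes, collapse = ", ")
              else "(intercepts only)"))
  print(format(x$coefficients[, c("term", "estimate", "se", "t", "p")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' Fit the full growth-curve mixed-effects model
#'
#' The full factorial model of recurrence rate on conversation type `c`,
#' task `k`, linear lag `l` and quadratic lag `q` (16 fixed effects:
#' intercept, 4 mains, and all interactions), with random intercepts for
#' dyad and conversation number and a backward-selected random-slope
#' structure shared by both groupings. In the standardized variant the
#' outcome is z-scored and predictors are scaled by their SDs so estimates
#' read as effect sizes.
#'
#' @param table A real-data table from [assemble_gca_table()].
#' @param standardized Fit the standardized variant?
#' @param slope_candidates Maximal random-slope candidate set; the default
#'   is the structure the deposited-study analysis retained (`c`, `l`, `q`,
#'   `k:c:l` for both groupings). Pass all 15 fixed terms for a fully
#'   maximal start.
#'
#' @return A `gca_fit`.
#' @export
fit_full_model <- function(table, standardized = FALSE,
                           slope_candidates = c("c", "l", "q", "k:c:l")) {
  if (!is.null(table$data) && length(unique(table$data)) > 1) {
    stop("table mixes real and surrogate rows; use ",
         "fit_baseline_contrast_models for the contrast analysis")
  }
  if (nlevels(factor(table$dyad)) < 2) stop("need at least 2 dyads")
  if (standardized) table <- standardize_gca(table, c("c", "k", "l", "q"))
  sel <- backward_select_random_slopes("c * k * l * q", table,
                                       slope_candidates)
  new_gca_fit(sel, if (standardized) "full_standardized" else "full",
              standardized, 16L)
}

#' Per-conversation post-hoc models
#'
#' Refits the growth-curve model within each conversation type separately:
#' fixed effects are task `k`, `l`, `q` and all their interactions (8
#' terms), with the same random-effect policy. If a subset contains a
#' single task level the model reduces to `l * q` (4 terms).
#'
#' @param table A real-data table from [assemble_gca_table()].
#' @param standardized Fit standardized variants (default `TRUE`)?
#' @param slope_candidates Maximal random-slope candidate set per subset.
#'
#' @return A list of `gca_fit`s named `affiliative` and `argumentative`.
#' @export
fit_posthoc_models <- function(table, standardized = TRUE,
                               slope_candidates = c("l", "q")) {
  fits <- lapply(c(affiliative = 0, argumentative = 1), function(cc) {
    sub <- table[table$c == cc, , drop = FALSE]
    if (nrow(sub) == 0) stop("no rows for conversation code ", cc)
    one_task <- length(unique(sub$k)) < 2
    if (standardized) {
      sub <- standardize_gca(sub, intersect(c("k", "l", "q"), names(sub)))
    }
    rhs <- if (one_task) "l * q" else "k * l * q"
    sel <- backward_select_random_slopes(rhs, sub, slope_candidates)
    new_gca_fit(sel,
                paste0("posthoc_c", cc, if (one_task) "_single_task" else ""),
                standardized, if (one_task) 4L else 8L)
  })
  fits
}

#' Real-versus-baseline contrast models
#'
#' Adds the `data` contrast (surrogate -0.5, real +0.5) and all its
#' interactions to the growth-curve model, doubling the fixed-effect
#' structure: 32 terms in the full contrast model, 16 in each
#' per-conversation contrast model. `data`-by-lag interactions quantify
#' profile structure beyond what the surrogates' own dynamics produce.
#'
#' @param table A table from [assemble_gca_table()] containing both real
#'   and surrogate rows.
#' @param standardized Standardized variant?
#' @param posthoc Also fit the per-conversation contrast models?
#' @param slope_candidates Maximal random-slope candidate set.
#'
#' @return A list with `full` and, when `posthoc = TRUE`, `affiliative`
#'   and `argumentative` `gca_fit`s.
#' @export
fit_baseline_contrast_models <- function(table, standardized = TRUE,
                                         posthoc = FALSE,
                                         slope_candidates = c("c", "l", "q")) {
  if (is.null(table$data) || length(unique(table$data)) < 2) {
    stop("contrast models need both real and surrogate rows; the data ",
         "factor and its interactions are undefined otherwise")
  }
  tb <- table
  if (standardized) tb <- standardize_gca(tb, c("c", "k", "l", "q", "data"))
  sel <- backward_select_random_slopes("data * c * k * l * q", tb,
                                       slope_candidates)
  out <- list(full = new_gca_fit(
    sel, if (standardized) "contrast_standardized" else "contrast",
    standardized, 32L))
  if (posthoc) {
    for (cc in c(affiliative = 0, argumentative = 1)) {
      nm <- names(which(c(affiliative = 0, argumentative = 1) == cc))
      sub <- table[table$c == cc, , drop = FALSE]
      if (standardized) sub <- standardize_gca(sub, c("k", "l", "q", "data"))
      sel_c <- backward_select_random_slopes(
        "data * k * l * q", sub, intersect(slope_candidates, c("l", "q")))
      out[[nm]] <- new_gca_fit(sel_c, paste0("contrast_", nm),
                               standardized, 16L)
    }
  }
  out
}
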