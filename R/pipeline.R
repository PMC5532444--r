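#' Read a participant-conversation movement CSV
#'
#' Strict reader for the `t_s,x,y,z` per-participant CSV format: the four
#' columns must be present, timestamps must be strictly increasing and
#' regular; extra columns are tolerated, ignored, and warned about.
#'
#' @param path CSV path.
#' @param participant,conversation Identifiers attached to the trace.
#'
#' @return An [accel_trace()].
#' @export
read_movement_csv <- function(path, participant = NA, conversation = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("t_s", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning(path, ": ignoring extra column(s) ",
            paste(extra, collapse = ", "))
  }
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) {
    stop(path, ": timestamps not strictly increasing at row ", bad[1] + 1L)
  }
  rate <- 1 / stats::median(diff(df$t_s))
  accel_trace(df$t_s, df$x, df$y, df$z, participant = participant,
              conversation = conversation,
              sample_rate_hz = round(rate))
}

#' Write a trace to the movement CSV format
#'
#' @param trace An [accel_trace()].
#' @param path Output path.
#' @export
write_movement_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t_s, x = trace$x, y = trace$y,
                              z = trace$z),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study as CSV files
#'
#' One `t_s,x,y,z` CSV per participant-conversation plus a study-level
#' `metadata.csv` with columns
#' `dyad,conversation,conv_type,conv_order,task,file_a,file_b`.
#'
#' @param study A `dyad_study`.
#' @param dir Output directory (created if needed).
#'
#' @return The metadata data frame, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in study$dyads) {
    for (cv in rec$conversations) {
      fa <- sprintf("dyad%02d_conv%d_a.csv", rec$dyad, cv$conv_num)
      fb <- sprintf("dyad%02d_conv%d_b.csv", rec$dyad, cv$conv_num)
      write_movement_csv(cv$a, file.path(dir, fa))
      write_movement_csv(cv$b, file.path(dir, fb))
      rows[[length(rows) + 1]] <- data.frame(
        dyad = rec$dyad, conversation = cv$conv_num,
        conv_type = cv$conv_type, conv_order = cv$conv_num,
        task = rec$task, file_a = fa, file_b = fb)
    }
  }
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a study back from CSV files
#'
#' @param dir Directory holding `metadata.csv` and the per-participant
#'   movement CSVs written by [write_study_csv()].
#'
#' @return A `dyad_study`.
#' @export
read_study_csv <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir)
  meta <- utils::read.csv(meta_path)
  dyad_ids <- sort(unique(meta$dyad))
  dyads <- lapply(dyad_ids, function(d) {
    md <- meta[meta$dyad == d, ]
    md <- md[order(md$conversation), ]
    conversations <- lapply(seq_len(nrow(md)), function(i) {
      list(a = read_movement_csv(file.path(dir, md$file_a[i]), "a",
                                 md$conversation[i]),
           b = read_movement_csv(file.path(dir, md$file_b[i]), "b",
                                 md$conversation[i]),
           conv_type = md$conv_type[i], conv_num = md$conversation[i])
    })
    structure(list(dyad = d, task = md$task[1],
                   conversations = conversations),
              class = "dyad_recording")
  })
  structure(list(design = NULL, dyads = dyads, metadata = meta),
            class = "dyad_study")
}

#' Cross-recurrence analysis of every conversation in a study
#'
#' Runs [run_crqa()] on each preprocessed dyad-conversation pair and
#' collects the profiles in the long format consumed by
#' [assemble_gca_table()], together with the per-conversation embedding
#' parameters.
#'
#' @param prepped A `prepped_study`.
#' @param target_rr Target overall recurrence rate.
#' @param max_lag Profile half-width in samples.
#' @param delay,dimension Optional fixed embedding parameters (estimated
#'   per conversation when `NULL`).
#'
#' @return A list: `drps` (long data frame, `source = "real"`) and
#'   `params` (`dyad`, `conversation`, `delay`, `dimension`, `radius`,
#'   `achieved_rr`).
#' @export
crqa_study <- function(prepped, target_rr = 0.05, max_lag = 50,
                       delay = NULL, dimension = NULL) {
  drps <- list()
  params <- list()
  for (cv in prepped$conversations) {
    res <- run_crqa(cv$a, cv$b, delay = delay, dimension = dimension,
                    target_rr = target_rr, max_lag = max_lag)
    drps[[length(drps) + 1]] <- data.frame(
      dyad = cv$dyad, conversation = cv$conversation,
      conv_type = cv$conv_type, task = cv$task,
      source = "real", surrogate_id = NA_integer_,
      lag = res$drp$lag, rr = res$drp$rr)
    params[[length(params) + 1]] <- data.frame(
      dyad = cv$dyad, conversation = cv$conversation,
      delay = res$params$delay, dimension = res$params$dimension,
      radius = res$params$radius, achieved_rr = res$rr)
  }
  list(drps = do.call(rbind, drps), params = do.call(rbind, params))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline; the defaults are the
#' study's analysis constants (10 Hz, 60-120 s calibration window, 5%
#' recurrence target, +/-50 lags, 10 phase-randomized surrogates).
#'
#' @param seed Master seed; every stage's randomness derives from it.
#' @param out_dir Results directory.
#' @param in_dir Optional input directory of study CSVs; when `NULL` a
#'   study is simulated from `design`.
#' @param design A [study_design()] used when simulating.
#' @param coupling,coupling_map,dropout Generator settings.
#' @param target_hz,calibration_window,target_rr,max_lag Analysis
#'   constants.
#' @param min_keep_s Inclusion threshold in seconds (4.5 min).
#' @param surrogate_method,n_surrogates Baseline settings.
#' @param delay,dimension Optional fixed embedding parameters.
#' @param standardized,posthoc,baseline_contrast Model options.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("dyadsync_"),
                            in_dir = NULL, design = study_design(seed = seed),
                            coupling = coupling_spec(),
                            coupling_map = default_coupling_map(),
                            dropout = dropout_spec(),
                            target_hz = 10, calibration_window = c(60, 120),
                            min_keep_s = 270,
                            target_rr = 0.05, max_lag = 50,
                            surrogate_method = "phase_randomization",
                            n_surrogates = 10,
                            delay = NULL, dimension = NULL,
                            standardized = TRUE, posthoc = TRUE,
                            baseline_contrast = TRUE) {
  design$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, in_dir = in_dir,
                 design = design, coupling = coupling,
                 coupling_map = coupling_map, dropout = dropout,
                 target_hz = target_hz,
                 calibration_window = calibration_window,
                 min_keep_s = min_keep_s,
                 target_rr = target_rr, max_lag = max_lag,
                 surrogate_method = surrogate_method,
                 n_surrogates = n_surrogates,
                 delay = delay, dimension = dimension,
                 standardized = standardized, posthoc = posthoc,
                 baseline_contrast = baseline_contrast),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or read), preprocess, CRQA,
#' surrogate baseline, growth-curve models — writing `drps.csv`,
#' `crqa_params.csv`, `cutoffs.csv`, `coefficients.csv`,
#' `slope_attempts.csv` and a `manifest.txt` with the resolved
#' configuration and per-stage row counts to `config$out_dir`. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stage <- "setup"
  tryCatch({
    set.seed(config$seed)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "simulate"
    study <- if (is.null(config$in_dir)) {
      message("simulate: ", config$design$n_dyads, " dyads")
      simulate_study(config$design, config$coupling, config$coupling_map,
                     config$dropout)
    } else {
      if (!dir.exists(config$in_dir)) {
        stop("input directory does not exist: ", config$in_dir)
      }
      message("read: ", config$in_dir)
      read_study_csv(config$in_dir)
    }

    stage <- "preprocess"
    prepped <- preprocess_study(study, config$target_hz,
                                config$calibration_window,
                                config$min_keep_s)
    message("preprocess: ", length(prepped$conversations), " conversations")
    utils::write.csv(prepped$cutoffs, file.path(config$out_dir, "cutoffs.csv"),
                     row.names = FALSE)

    stage <- "crqa"
    real <- crqa_study(prepped, config$target_rr, config$max_lag,
                       config$delay, config$dimension)
    message("crqa: ", nrow(real$drps), " profile rows")
    utils::write.csv(real$params,
                     file.path(config$out_dir, "crqa_params.csv"),
                     row.names = FALSE)

    stage <- "surrogate"
    surr <- build_baseline_drps(prepped, real$params,
                                config$surrogate_method,
                                config$n_surrogates, config$max_lag)
    message("surrogate: ", nrow(surr), " baseline rows")
    drps <- rbind(real$drps, surr)
    utils::write.csv(drps, file.path(config$out_dir, "drps.csv"),
                     row.names = FALSE)

    stage <- "model"
    tab_real <- assemble_gca_table(real$drps)
    fits <- list(full = fit_full_model(tab_real, config$standardized))
    if (config$posthoc) {
      fits <- c(fits, fit_posthoc_models(tab_real, config$standardized))
    }
    if (config$baseline_contrast) {
      tab_all <- assemble_gca_table(drps)
      fits$contrast <- fit_baseline_contrast_models(
        tab_all, config$standardized)$full
    }
    coefs <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
    utils::write.csv(coefs, file.path(config$out_dir, "coefficients.csv"),
                     row.names = FALSE)
    attempts <- do.call(rbind, lapply(names(fits), function(nm) {
      cbind(model = nm, fits[[nm]]$attempts)
    }))
    utils::write.csv(attempts,
                     file.path(config$out_dir, "slope_attempts.csv"),
                     row.names = FALSE)

    manifest <- c(
      sprintf("dyadsync_version: %s",
              as.character(utils::packageVersion("dyadsync"))),
      sprintf("seed: %d", config$seed),
      sprintf("n_dyads: %d", length(study$dyads)),
      sprintf("target_hz: %g", config$target_hz),
      sprintf("calibration_window: %g-%g", config$calibration_window[1],
              config$calibration_window[2]),
      sprintf("target_rr: %g", config$target_rr),
      sprintf("max_lag: %d", config$max_lag),
      sprintf("surrogate_method: %s", config$surrogate_method),
      sprintf("n_surrogates: %d", config$n_surrogates),
      sprintf("rows_real_drp: %d", nrow(real$drps)),
      sprintf("rows_surrogate_drp: %d", nrow(surr)),
      sprintf("rows_coefficients: %d", nrow(coefs)))
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

    invisible(list(study = study, prepped = prepped, drps = drps,
                   params = real$params, fits = fits,
                   out_dir = config$out_dir))
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
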