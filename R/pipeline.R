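#' Build and validate a pipeline run configuration
#'
#' A run either simulates a recording (block `simulate`) or loads existing
#' per-step record files (block `input`). Unknown keys anywhere in the
#' configuration are fatal; every random stage takes its seed from the
#' mandatory top-level `seed`, which is recorded in the run manifest.
#'
#' Recognized keys:
#' \describe{
#'   \item{seed}{integer, mandatory.}
#'   \item{simulate}{`preset` (healthy/hfref), `spontaneous_hr`,
#'     `step_duration` (s), `sampling_rate` (Hz), `snr_db`, plus any
#'     argument of [coupling_config()].}
#'   \item{input}{`paths` (character vector of record files),
#'     `format` (csv/edf/auto).}
#'   \item{segmentation}{`envelope_method`, `envelope_window`,
#'     `stable_min_duration` (s, `NULL` disables stability selection),
#'     `stable_tolerance`.}
#'   \item{spectrogram}{any argument of [spectro_config()].}
#'   \item{regression}{`rmse_denominator`, `interval`.}
#'   \item{output}{`dir`, `write_signals` (logical).}
#' }
#'
#' @param config nested list, or path to a YAML/JSON config file.
#' @return a validated `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  allowed <- list(
    seed = NULL,
    simulate = c("preset", "spontaneous_hr", "step_duration",
                 "sampling_rate", "snr_db", "sigma", "rho", "rr_jitter",
                 "ptt_intercept", "ptt_slope", "s1_gain", "s2_gain",
                 "gain_dpdt_coeff", "freq_edp_coeff", "gain_esp_coeff",
                 "freq_esp_coeff", "diastolic_sound", "diastolic_gain"),
    input = c("paths", "format"),
    segmentation = c("envelope_method", "envelope_window",
                     "stable_min_duration", "stable_tolerance"),
    spectrogram = c("frame", "hop", "n_mels", "fmin", "fmax", "n_mfcc",
                    "mfcc_offset"),
    regression = c("rmse_denominator", "interval"),
    output = c("dir", "write_signals")
  )
  unknown_top <- setdiff(names(config), names(allowed))
  assert_that(length(unknown_top) == 0L,
              sprintf("unknown config key(s): %s",
                      paste(unknown_top, collapse = ", ")))
  for (block in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[block]]), allowed[[block]])
    assert_that(length(bad) == 0L,
                sprintf("unknown config key(s) in '%s': %s",
                        block, paste(bad, collapse = ", ")))
  }
  assert_that(!is.null(config$seed) && is_scalar_number(config$seed),
              "config requires an integer 'seed' (no wall-clock defaults)")
  assert_that(!is.null(config$simulate) || !is.null(config$input),
              "config requires a 'simulate' or 'input' block")
  structure(config, class = "run_config")
}

#' Run the full pipeline: signals to regression tables
#'
#' Simulates (or loads) the per-step recordings, segments every step from
#' the MED signal, extracts features and invasive indices, fits the
#' per-step regressions and writes all tabular outputs plus a manifest to
#' the output directory. Re-running with the same configuration and seed
#' reproduces the numeric outputs.
#'
#' Written files: `signals_<step>.csv` (simulated runs, optional),
#' `ground_truth.csv` (simulated runs), `segmentation.csv`,
#' `features.csv`, `indices.csv`, `results.csv`, `results.json`
#' (coefficients and confidence-bound grids), `summary.md`, `run.log`,
#' `manifest.json`.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (overrides `config$output$dir`;
#'   default `"phonopress_run"`).
#' @return the output directory, invisibly; the results table is attached
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  out_dir <- out_dir %||% cfg$output$dir %||% "phonopress_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logit <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  seed <- as.integer(cfg$seed)
  logit("phonopress pipeline, seed %d", seed)
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sb <- cfg$simulate
    proto <- default_protocol(
      spontaneous_hr = sb$spontaneous_hr %||% 78,
      step_duration = sb$step_duration %||% 180
    )
    cc_args <- sb[intersect(names(sb), names(formals(coupling_config)))]
    coupling <- do.call(coupling_config, cc_args)
    preset <- hemodynamic_preset(sb$preset %||% "hfref")
    noise <- noise_config(sb$snr_db %||% 20)
    sim <- simulate_recording(proto, preset, coupling, noise,
                              sampling_rate = sb$sampling_rate %||% 1000,
                              seed = seed)
    records <- sim$records
    truth <- sim$truth
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    if (isTRUE(cfg$output$write_signals)) {
      for (step in names(records)) {
        write_record(records[[step]],
                     file.path(out_dir, sprintf("signals_%s.csv", step)),
                     format = "csv")
      }
    }
    logit("simulated %d steps (%s preset)", length(records), preset$label)
  } else {
    paths <- cfg$input$paths
    records <- stats::setNames(
      lapply(paths, read_record, format_hint = cfg$input$format %||% "auto"),
      vapply(paths, function(p) read_record(p)$step_label, character(1))
    )
    logit("loaded %d record(s)", length(records))
  }
  seg_cfg <- cfg$segmentation %||% list()
  eval_cfg <- list(
    envelope_method = seg_cfg$envelope_method %||% "sliding_extrema",
    envelope_window = seg_cfg$envelope_window %||% 0.05,
    spectro = do.call(spectro_config,
                      cfg$spectrogram %||% list()),
    rmse_denominator = cfg$regression$rmse_denominator %||%
      "n_minus_p_minus_1",
    interval = cfg$regression$interval %||% "confidence"
  )
  seg_rows <- list(); feat_rows <- list(); idx_rows <- list()
  res_rows <- list(); fits_json <- list()
  for (step in names(records)) {
    rec <- records[[step]]
    if (!is.null(seg_cfg$stable_min_duration)) {
      rp0 <- detect_r_peaks(rec$channels$ECG, rec$sampling_rate)
      win <- select_stable_segment(
        rec, rp0,
        min_duration = seg_cfg$stable_min_duration,
        tolerance = seg_cfg$stable_tolerance %||% 0.10
      )
      rec$channels <- lapply(rec$channels, function(x) x[win$start:win$end])
      logit("step %s: stable window %d..%d (%d beats)", step,
            win$start, win$end, win$n_beats)
    }
    ev <- evaluate_step(rec, eval_cfg)
    stages <- attr(ev, "stages")
    if (!is.null(stages)) {
      b <- stages$segmentation$beats
      fs <- rec$sampling_rate
      seg_rows[[step]] <- data.frame(
        step = step, beat_index = b$beat,
        r_onset_s = (b$onset - 1L) / fs,
        boundary_s = (b$boundary - 1L) / fs,
        r_end_s = (b$end - 1L) / fs,
        valid = b$valid, reason = b$reason, stringsAsFactors = FALSE
      )
      feat_rows[[step]] <- data.frame(step = step,
                                      as.data.frame(stages$features),
                                      stringsAsFactors = FALSE)
      ix <- as.data.frame(stages$indices)
      names(ix) <- c("beat_index", "edp_mmHg", "esp_mmHg",
                     "dpdtmax_mmHg_s", "edp_time_s", "esp_time_s",
                     "dpdtmax_time_s")
      idx_rows[[step]] <- data.frame(step = step, ix,
                                     stringsAsFactors = FALSE)
      invalid <- b[!b$valid, , drop = FALSE]
      logit("step %s: %d beats, %d invalid (%s)", step, nrow(b),
            nrow(invalid),
            if (nrow(invalid) > 0L)
              paste(unique(invalid$reason), collapse = ",") else "-")
    } else {
      logit("step %s: stage failure -> not_available", step)
    }
    res_rows[[step]] <- as.data.frame(ev)
    fits <- attr(ev, "fits")
    fits_json[[step]] <- lapply(fits, function(f) {
      list(target = f$target, predictor_set = f$predictor_set,
           n_beats = f$n_beats, status = f$status,
           r_squared = f$r_squared, rmse = f$rmse,
           coefficients = as.list(f$coefficients),
           ci95 = f$ci95)
    })
  }
  results <- do.call(rbind, c(res_rows, make.row.names = FALSE))
  utils::write.csv(do.call(rbind, c(seg_rows, make.row.names = FALSE)),
                   file.path(out_dir, "segmentation.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, c(feat_rows, make.row.names = FALSE)),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, c(idx_rows, make.row.names = FALSE)),
                   file.path(out_dir, "indices.csv"), row.names = FALSE)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(fits_json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  writeLines(report_summary(results), file.path(out_dir, "summary.md"))
  manifest <- list(
    package = "phonopress",
    version = as.character(utils::packageVersion("phonopress")),
    seed = seed,
    config = unclass(cfg),
    config_hash = digest_config(cfg),
    n_steps = length(records),
    created = "fixed-by-seed"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logit("wrote results for %d step(s) to %s", length(records), out_dir)
  structure(invisible(out_dir), results = results)
}

# Deterministic config fingerprint (no external digest dependency).
#' @noRd
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  raw <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Render a per-step markdown summary of regression results
#'
#' One table per step (target, predictor set, n, R-squared, RMSE); rows
#' with `status = "not_available"` render as "not available". Flags any
#' step where the in-sample nested-model ordering R2(full) >= R2(invPTT)
#' is violated (which the fitting stage guarantees never happens).
#'
#' @param results data frame from [evaluate_protocol()]/[run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report_summary <- function(results) {
  assert_that(is.data.frame(results) && nrow(results) > 0L,
              "empty results; nothing to report",
              "phonopress_empty_report_error")
  lines <- c("# Left-ventricular pressure-index prediction", "")
  for (step in unique(results$step_label)) {
    sub <- results[results$step_label == step, , drop = FALSE]
    lines <- c(lines, sprintf("## Step: %s", step), "",
               "| target | predictors | n | R2 | RMSE |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines, if (r$status == "ok") {
        sprintf("| %s | %s | %d | %.3f | %.3f |",
                r$target, r$predictor_set, r$n_beats, r$r_squared, r$rmse)
      } else {
        sprintf("| %s | %s | %s | not available | not available |",
                r$target, r$predictor_set,
                if (r$n_beats > 0L) as.character(r$n_beats) else "-")
      })
    }
    viol <- violated_nesting(sub)
    if (length(viol) > 0L) {
      lines <- c(lines, "",
                 sprintf("**WARNING**: nested-model R2 ordering violated for %s",
                         paste(viol, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @noRd
violated_nesting <- function(sub) {
  viol <- character(0)
  for (target in unique(sub$target)) {
    r1 <- sub[sub$target == target & sub$predictor_set == "invPTT", ]
    r2 <- sub[sub$target == target &
                sub$predictor_set == "setAB_plus_invPTT", ]
    if (nrow(r1) == 1L && nrow(r2) == 1L &&
        identical(r1$status, "ok") && identical(r2$status, "ok") &&
        r2$r_squared < r1$r_squared - 1e-10) {
      viol <- c(viol, target)
    }
  }
  viol
}
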