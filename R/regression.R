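TARGETS <- c("EDP", "ESP", "dPdt_max")
PREDICTOR_SETS <- c("invPTT", "setAB_plus_invPTT")

#' Align beat-phase features with their target index
#'
#' Implements the prediction strategy: the systolic sounds predict the
#' preceding end-diastolic pressure (EDP) and the contemporary dPdt_max,
#' while the diastolic sounds predict the preceding end-systolic pressure
#' (ESP). invPTT is attached to every target. Rows with any invalid or
#' missing entry are dropped.
#'
#' @param features a `beat_feature_table` from [assemble_feature_table()].
#' @param indices a `pressure_indices` from [extract_pressure_indices()].
#' @param target `"EDP"`, `"ESP"` or `"dPdt_max"`.
#' @return a design data frame: column `response` plus exactly 18 predictor
#'   columns (`invptt`, 4 set A, 13 set B of the target's phase).
#' @export
align_beat_targets <- function(features, indices,
                               target = c("EDP", "ESP", "dPdt_max")) {
  target <- match.arg(target)
  phase <- if (target == "ESP") "dia" else "sys"
  resp_col <- switch(target, EDP = "edp", ESP = "esp", dPdt_max = "dpdtmax")
  pred_cols <- c("invptt",
                 paste0(phase, "A_", c("flux", "kurtosis", "skewness",
                                       "slope")),
                 sprintf("%sB_dd%02d", phase, 0:12))
  feats <- features[isTRUE_vec(features$valid), , drop = FALSE]
  m <- merge(feats[, c("beat", pred_cols)],
             indices[, c("beat", resp_col)], by = "beat")
  if (nrow(m) == 0L) {
    warning("no complete beats for target ", target)
  }
  design <- data.frame(response = m[[resp_col]],
                       m[, pred_cols, drop = FALSE])
  complete <- stats::complete.cases(design)
  design <- design[complete, , drop = FALSE]
  if (nrow(design) == 0L) warning("design for ", target, " is empty")
  attr(design, "target") <- target
  attr(design, "phase") <- phase
  design
}

#' @noRd
isTRUE_vec <- function(x) !is.na(x) & x

#' Ordinary least-squares fit of a design table
#'
#' Fits the response on either invPTT alone or on all 18 predictors, with
#' intercept. Predictors are standardized internally for conditioning;
#' coefficients are reported on the original scale. `r_squared` is the
#' in-sample coefficient of determination; `rmse` defaults to the residual
#' standard error `sqrt(SSres / (n - p - 1))` (flag `rmse_denominator =
#' "n"` for the plain `sqrt(SSres / n)`). The 95% bounds are pointwise
#' mean-prediction bounds of the regression of the response on the fitted
#' linear combination (the "whole model" axis), on a 100-point grid
#' (`interval = "prediction"` gives prediction bounds instead).
#'
#' Rank deficiency or `n < p + 2` yields `status = "not_available"` with
#' numeric fields absent (`NA`).
#'
#' @param design data frame from [align_beat_targets()] (or any data frame
#'   with a `response` column and predictor columns).
#' @param predictor_subset `"invPTT_only"` or `"all18"`.
#' @param rmse_denominator `"n_minus_p_minus_1"` (default) or `"n"`.
#' @param interval `"confidence"` (default) or `"prediction"`.
#' @return a `regression_result` list: `target`, `predictor_set`,
#'   `n_beats`, `coefficients` (named, incl. `(Intercept)`), `r_squared`,
#'   `rmse`, `ci95` (data frame `score`, `fit`, `lower`, `upper`),
#'   `status`.
#' @export
fit_ols <- function(design, predictor_subset = c("all18", "invPTT_only"),
                    rmse_denominator = c("n_minus_p_minus_1", "n"),
                    interval = c("confidence", "prediction")) {
  predictor_subset <- match.arg(predictor_subset)
  rmse_denominator <- match.arg(rmse_denominator)
  interval <- match.arg(interval)
  pred_cols <- setdiff(names(design), "response")
  if (predictor_subset == "invPTT_only") pred_cols <- "invptt"
  set_label <- if (predictor_subset == "invPTT_only") "invPTT"
               else "setAB_plus_invPTT"
  target <- attr(design, "target")
  na_result <- function(reason) {
    structure(list(target = target, predictor_set = set_label,
                   n_beats = nrow(design), coefficients = NULL,
                   r_squared = NA_real_, rmse = NA_real_, ci95 = NULL,
                   status = "not_available", reason = reason),
              class = "regression_result")
  }
  n <- nrow(design)
  p <- length(pred_cols)
  if (n < p + 2L) return(na_result("n_too_small"))
  y <- design$response
  X <- as.matrix(design[, pred_cols, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0)) return(na_result("rank_deficient"))
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < p + 1L) return(na_result("rank_deficient"))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), y)
  beta_std <- fit$coefficients
  beta <- beta_std[-1L] / sdv
  intercept <- beta_std[1L] - sum(beta * mu)
  fitted <- as.numeric(cbind(1, X) %*% c(intercept, beta))
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    warning("zero-variance response; reporting r_squared = 0")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  rmse <- if (rmse_denominator == "n") sqrt(ss_res / n)
          else sqrt(ss_res / (n - p - 1L))
  # 95% bounds along the whole-model (fitted linear combination) axis
  ci <- NULL
  if (stats::var(fitted) > 0) {
    z <- fitted
    zbar <- mean(z)
    szz <- sum((z - zbar)^2)
    b1 <- sum((z - zbar) * (y - mean(y))) / szz
    b0 <- mean(y) - b1 * zbar
    s2 <- sum((y - (b0 + b1 * z))^2) / (n - 2L)
    grid <- seq(min(z), max(z), length.out = 100L)
    extra <- if (interval == "prediction") 1 else 0
    se <- sqrt(s2 * (extra + 1 / n + (grid - zbar)^2 / szz))
    tq <- stats::qt(0.975, n - 2L)
    ci <- data.frame(score = grid, fit = b0 + b1 * grid,
                     lower = b0 + b1 * grid - tq * se,
                     upper = b0 + b1 * grid + tq * se)
  }
  structure(
    list(target = target, predictor_set = set_label, n_beats = n,
         coefficients = c(`(Intercept)` = unname(intercept),
                          stats::setNames(beta, pred_cols)),
         r_squared = r2, rmse = rmse, ci95 = ci, status = "ok",
         reason = NA_character_),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<regression_result> %s ~ %s: n=%d R2=%.3f RMSE=%.3f\n",
                x$target %||% "?", x$predictor_set, x$n_beats,
                x$r_squared, x$rmse))
  } else {
    cat(sprintf("<regression_result> %s ~ %s: not available (%s)\n",
                x$target %||% "?", x$predictor_set, x$reason))
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate one pacing step: 3 targets x 2 predictor sets
#'
#' Runs the full per-step analysis on one [signal_record()] that includes
#' the invasive LVP channel: segmentation, feature extraction, index
#' extraction, target alignment and the two nested OLS fits per target.
#' In-sample R-squared of the full model is never below that of the
#' invPTT-only model (nested least squares); this is asserted on every run.
#'
#' @param record a [signal_record()] with LVP.
#' @param cfg optional list of parameter overrides: `spectro` (a
#'   [spectro_config()]), `envelope_method`, `envelope_window`,
#'   `rmse_denominator`, `interval`, `smooth_window`.
#' @return a `step_evaluation`: data frame with 6 rows (`step_label`,
#'   `target`, `predictor_set`, `n_beats`, `r_squared`, `rmse`, `status`,
#'   `reason`); the full `regression_result` objects are in
#'   `attr(, "fits")`, the intermediate segmentation/features/indices in
#'   `attr(, "stages")`.
#' @export
evaluate_step <- function(record, cfg = list()) {
  cfg_spectro <- cfg$spectro %||% spectro_config()
  step <- record$step_label
  not_avail <- function(reason) {
    out <- expand.grid(target = TARGETS, predictor_set = PREDICTOR_SETS,
                       stringsAsFactors = FALSE)
    out <- data.frame(step_label = step, out,
                      n_beats = 0L, r_squared = NA_real_, rmse = NA_real_,
                      status = "not_available", reason = reason,
                      stringsAsFactors = FALSE)
    structure(out, class = c("step_evaluation", "data.frame"))
  }
  stages <- tryCatch({
    assert_that("LVP" %in% names(record$channels),
                "LVP channel required for evaluation",
                "phonopress_channel_missing_error")
    sr <- segment_record(record,
                         envelope_method = cfg$envelope_method %||%
                           "sliding_extrema",
                         envelope_window = cfg$envelope_window %||% 0.05)
    seg <- sr$segmentation
    indices <- extract_pressure_indices(record$channels$LVP, seg,
                                        record$sampling_rate,
                                        smooth_window = cfg$smooth_window %||%
                                          5L)
    features <- assemble_feature_table(seg, record$channels$MIC,
                                       record$channels$POX,
                                       record$sampling_rate, cfg_spectro)
    list(segmentation = seg, med = sr$med, indices = indices,
         features = features)
  }, phonopress_error = function(e) e)
  if (inherits(stages, "error")) {
    return(not_avail(conditionMessage(stages)))
  }
  rows <- list()
  fits <- list()
  for (target in TARGETS) {
    design <- align_beat_targets(stages$features, stages$indices, target)
    for (ps in c("invPTT_only", "all18")) {
      fit <- fit_ols(design, ps,
                     rmse_denominator = cfg$rmse_denominator %||%
                       "n_minus_p_minus_1",
                     interval = cfg$interval %||% "confidence")
      fits[[paste(target, ps, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        step_label = step, target = target,
        predictor_set = fit$predictor_set, n_beats = fit$n_beats,
        r_squared = fit$r_squared, rmse = fit$rmse, status = fit$status,
        reason = fit$reason, stringsAsFactors = FALSE
      )
    }
    f1 <- fits[[paste(target, "invPTT_only", sep = ".")]]
    f2 <- fits[[paste(target, "all18", sep = ".")]]
    if (f1$status == "ok" && f2$status == "ok" &&
        f2$r_squared < f1$r_squared - 1e-10) {
      stop_phonopress(
        sprintf("nested-model violation for %s: R2(all18)=%.6f < R2(invPTT)=%.6f",
                target, f2$r_squared, f1$r_squared),
        "phonopress_internal_error"
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("step_evaluation", "data.frame"),
            fits = fits, stages = stages)
}

#' Evaluate every step of a simulated or loaded protocol
#'
#' @param records named list of [signal_record()] (one per step).
#' @param cfg see [evaluate_step()].
#' @return data frame with 6 rows per step (row-bound step evaluations).
#' @export
evaluate_protocol <- function(records, cfg = list()) {
  res <- lapply(records, function(r) {
    ev <- evaluate_step(r, cfg)
    as.data.frame(ev)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  structure(out, class = c("protocol_evaluation", "data.frame"))
}

#' Published reference regression results
#'
#' The R-squared / RMSE tables reported for the two instrumented minipigs
#' (HFrEF and healthy control) across the five pacing steps, as shipped
#' with the package for reporting and comparison. These are reference
#' values from the original animal experiments, not outputs of the
#' simulator.
#'
#' @return data frame: `subject`, `pacing`, `target`, `predictors`, `r2`,
#'   `rmse`, `status`.
#' @export
published_reference_results <- function() {
  path <- system.file("extdata", "published_regression_results.csv",
                      package = "phonopress", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
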