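toy_features <- function() {
  # 3 beats, the middle one invalidated; only structure matters
  tab <- sim_step_features()$table[1:3, ]
  tab$valid <- c(TRUE, FALSE, TRUE)
  tab
}

# ---------------------------------------------------------------------------

test_that("target alignment follows the systolic/diastolic strategy", {
  st <- sim_step_features()
  for (target in c("EDP", "ESP", "dPdt_max")) {
    d <- align_beat_targets(st$table, st$indices, target)
    expect_equal(ncol(d) - 1L, 18L)    # 18 predictors + response
    phase <- if (target == "ESP") "dia" else "sys"
    expect_true(all(grepl(paste0("^(invptt|", phase, ")"),
                          setdiff(names(d), "response"))))
  }
  # responses trace back to the extracted indices beat by beat
  d_esp <- align_beat_targets(st$table, st$indices, "ESP")
  common <- intersect(st$table$beat[st$table$valid], st$indices$beat)
  expect_equal(d_esp$response,
               st$indices$esp[match(common, st$indices$beat)])

  # invalid beats are dropped
  tab3 <- toy_features()
  ix3 <- st$indices[st$indices$beat %in% tab3$beat, ]
  d3 <- align_beat_targets(tab3, ix3, "EDP")
  expect_equal(nrow(d3), 2L)
})

test_that("OLS matches the normal-equations oracle", {
  withr::with_seed(23, {
    X <- matrix(stats::rnorm(90), nrow = 30, ncol = 3)
    y <- 2 + X %*% c(1, -0.5, 0.25) + stats::rnorm(30, sd = 0.3)
  })
  d <- data.frame(response = as.numeric(y), invptt = X[, 1], a = X[, 2],
                  b = X[, 3])
  fit <- fit_ols(d, "all18")
  want <- oracle_ols(as.numeric(y), X)
  expect_equal(unname(fit$coefficients), want$beta, tolerance = 1e-8)
  expect_equal(fit$r_squared, want$r2, tolerance = 1e-8)
  expect_equal(fit$rmse, want$rmse, tolerance = 1e-8)
  # plain-n RMSE variant
  fit_n <- fit_ols(d, "all18", rmse_denominator = "n")
  expect_equal(fit_n$rmse, want$rmse * sqrt((30 - 4) / 30), tolerance = 1e-8)
})

test_that("perfect and degenerate fits behave by contract", {
  x <- seq_len(50)
  d <- data.frame(response = 2 * x + 1, invptt = x)
  fit <- fit_ols(d, "invPTT_only")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)

  # too few observations for 18 predictors
  st <- sim_step_features()
  d18 <- align_beat_targets(st$table, st$indices, "EDP")[1:10, ]
  fit18 <- fit_ols(d18, "all18")
  expect_equal(fit18$status, "not_available")
  expect_true(is.na(fit18$rmse))

  # rank deficiency
  d2 <- data.frame(response = stats::rnorm(30), invptt = 1:30, dup = 1:30)
  expect_equal(fit_ols(d2, "all18")$status, "not_available")

  # zero-variance response
  d3 <- data.frame(response = rep(5, 30), invptt = stats::rnorm(30))
  expect_warning(f3 <- fit_ols(d3, "invPTT_only"), "zero-variance")
  expect_equal(f3$r_squared, 0)
})

test_that("confidence bounds straddle the fitted line on a 100-point grid", {
  withr::with_seed(29, {
    x <- stats::rnorm(80)
    d <- data.frame(response = 1 + 2 * x + stats::rnorm(80, sd = 0.5),
                    invptt = x)
  })
  fit <- fit_ols(d, "invPTT_only")
  expect_equal(nrow(fit$ci95), 100L)
  expect_true(all(fit$ci95$lower < fit$ci95$fit))
  expect_true(all(fit$ci95$upper > fit$ci95$fit))
  # prediction bounds are wider
  fitp <- fit_ols(d, "invPTT_only", interval = "prediction")
  expect_true(all(fitp$ci95$upper - fitp$ci95$lower >
                    fit$ci95$upper - fit$ci95$lower))
})

test_that("a full step evaluation yields six rows with nested R2 ordering", {
  st <- sim_step_features()
  ev <- evaluate_step(st$record)
  expect_equal(nrow(ev), 6L)
  expect_setequal(unique(ev$target), c("EDP", "ESP", "dPdt_max"))
  for (target in unique(ev$target)) {
    r_iv <- ev$r_squared[ev$target == target & ev$predictor_set == "invPTT"]
    r_full <- ev$r_squared[ev$target == target &
                             ev$predictor_set == "setAB_plus_invPTT"]
    expect_gte(r_full, r_iv)
  }
})

test_that("a record with no usable beats reports six not-available rows", {
  rec <- signal_record(
    channels = list(ECG = rep(0, 5000), LVP = rep(10, 5000),
                    MIC = rep(0, 5000), POX = rep(40, 5000)),
    sampling_rate = 1000, step_label = "flatline"
  )
  ev <- suppressWarnings(evaluate_step(rec))
  expect_equal(nrow(ev), 6L)
  expect_true(all(ev$status == "not_available"))
})

test_that("coefficients recover a known linear data-generating process", {
  # response built as a known linear combination of extracted features
  st <- sim_step_features()
  d <- align_beat_targets(st$table, st$indices, "EDP")
  X <- as.matrix(d[, setdiff(names(d), "response")])
  Z <- scale(X)
  withr::with_seed(31, {
    truth_beta <- stats::rnorm(ncol(Z))
    y <- as.numeric(Z %*% truth_beta) + stats::rnorm(nrow(Z), sd = 0.1)
  })
  d2 <- d
  d2$response <- y
  fit <- fit_ols(d2, "all18")
  got_std <- fit$coefficients[-1] * apply(X, 2, stats::sd)
  expect_gt(fit$r_squared, 0.9)
  # sampling-theory bound: Var(beta_hat) = sigma^2 diag((Z'Z)^-1); the
  # mel features are strongly collinear, so the conditioning enters here
  Zi <- cbind(1, Z)
  v <- 0.1^2 * diag(solve(t(Zi) %*% Zi))[-1]
  expect_lt(sqrt(mean((got_std - truth_beta)^2)), 3 * sqrt(mean(v)))
})
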