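test_that("percent-signal-change conversion is correct and guarded", {
  tms <- seq(0, 357, by = 3)
  const <- bold_series(tms, rep(250, length(tms)))
  pct <- to_percent_change(const)
  expect_equal(unique(pct$bold), 0)
  expect_equal(bold_units(pct), "percent")

  # s0 = 100, plateau at 102 -> 2%
  vals <- ifelse(tms < 60, 100, 102)
  pct2 <- to_percent_change(bold_series(tms, vals), c(0, 59))
  expect_equal(max(pct2$bold), 2)

  # applying twice errors (idempotence guard)
  expect_error(to_percent_change(pct), "already")
  expect_error(to_percent_change(bold_series(tms, rep(-5, length(tms)))),
               "positive")
})

make_reg <- function(seed = 1, tau = 0) {
  sim <- quick_sim(tau = tau, seed = seed)
  list(sim = sim,
       reg = build_regressor(sim$truth, seq(0, 357, by = 3)))
}

test_that("the CVR GLM recovers exact linear combinations", {
  r <- make_reg()
  reg <- r$reg
  # bold = 2 x regressor + 5, no noise -> exact coefficients
  y <- bold_series(reg$time, 2 * reg$normalized + 5, units = "percent")
  fit <- suppressWarnings(fit_cvr_glm(y, reg, drift_order = 0))
  expect_equal(unname(coef(fit$model)), c(5, 2), tolerance = 1e-10)

  # plus linear drift 0.01/s absorbed by the drift column
  y2 <- bold_series(reg$time, 2 * reg$normalized + 5 + 0.01 * reg$time,
                    units = "percent")
  fit2 <- suppressWarnings(fit_cvr_glm(y2, reg, drift_order = 1))
  expect_equal(coef(fit2$model)[["regressor"]], 2, tolerance = 1e-10)
})

test_that("GLM standard errors match the closed-form OLS oracle", {
  r <- make_reg()
  reg <- r$reg
  set.seed(42)
  y <- bold_series(reg$time, 3 * reg$normalized + rnorm(nrow(reg), 0, 0.5),
                   units = "percent")
  fit <- fit_cvr_glm(y, reg, drift_order = 1)
  # normal-equation oracle with the residual variance estimate
  X <- cbind(1, reg$normalized, reg$time / 100)
  bhat <- solve(t(X) %*% X, t(X) %*% y$bold)
  res <- y$bold - X %*% bhat
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se_oracle <- sqrt(s2 * diag(solve(t(X) %*% X)))
  s <- summary(fit$model)$coefficients
  expect_equal(unname(s[, "Estimate"]), as.numeric(bhat), tolerance = 1e-8)
  expect_equal(unname(s[, "Std. Error"]), unname(se_oracle),
               tolerance = 1e-8)
  # residual orthogonality to the design
  expect_lt(max(abs(t(X) %*% stats::residuals(fit$model))), 1e-8)
})

test_that("CVR conversion divides the percent-units beta by the trace maximum", {
  r <- make_reg()
  reg <- r$reg
  # percent-units fit with beta 9.6 and trace max 48 -> 0.2 %/mmHg
  y <- bold_series(reg$time, 9.6 * reg$normalized, units = "percent")
  fit <- suppressWarnings(fit_cvr_glm(y, reg, drift_order = 0))
  expect_equal(attr(reg, "trace_max"), 48)
  expect_equal(cvr_from_fit(fit), 9.6 / 48, tolerance = 1e-10)
})

test_that("normalized and raw-mmHg regressor parameterizations agree", {
  sim <- quick_sim(tau = 10, seed = 6)
  acq <- acquisition_spec(3, 120)
  bold <- simulate_bold(sim$truth,
                        voxel_model(s0 = 400, true_cvr = 0.21,
                                    drift_linear = 0.02, noise_sd = 3,
                                    ar1_coefficient = 0.3),
                        acq, seed = 6)
  et <- extract_end_tidal(sim$trace)
  reg <- build_regressor(et, bold$time)
  pct <- to_percent_change(bold, c(0, 55))
  fit <- fit_cvr_glm(pct, reg, drift_order = 1)
  cvr_norm <- cvr_from_fit(fit)
  # direct regression of percent BOLD on the raw mmHg interpolant
  direct <- lm(pct$bold ~ reg$raw_mmHg + I(reg$time / 100))
  expect_equal(cvr_norm, unname(coef(direct)[2]), tolerance = 1e-9)
})

test_that("noiseless end-to-end pipeline recovers planted CVR to 1e-9", {
  sim <- quick_sim(tau = 0, seed = 2)
  acq <- acquisition_spec(3, 120)
  bold <- simulate_bold(sim$truth,
                        voxel_model(s0 = 500, true_cvr = 0.25,
                                    drift_linear = 0.01),
                        acq, seed = 2)
  res <- suppressWarnings(estimate_cvr(sim$trace, bold))
  expect_equal(res$cvr, 0.25, tolerance = 1e-9)
  expect_equal(res$delta_etco2, 8)
  expect_true(res$qc_pass)
})

test_that("voxelwise maps recover planted per-voxel CVR within the mask", {
  sim <- quick_sim(tau = 0, seed = 2)
  acq <- acquisition_spec(3, 120)
  cvr_arr <- array(0.3, c(2, 2, 1))
  cvr_arr[1, 2, 1] <- 0.1
  vol <- simulate_bold_volume(sim$truth, cvr_arr, acq,
                              voxel_model(s0 = 300), seed = 9)
  reg <- build_regressor(sim$truth, acquisition_times(acq))
  mask <- array(TRUE, c(2, 2, 1))
  mask[2, 2, 1] <- FALSE
  map <- suppressWarnings(
    fit_cvr_map(vol, reg, mask, drift_order = 0, baseline_window = c(0, 55))
  )
  expect_equal(map$cvr[1, 1, 1], 0.3, tolerance = 1e-9)
  expect_equal(map$cvr[1, 2, 1], 0.1, tolerance = 1e-9)
  expect_true(is.na(map$cvr[2, 2, 1])) # outside mask: undefined
  expect_error(fit_cvr_map(vol, reg, array(FALSE, c(2, 2, 1))), "empty")
  expect_error(fit_cvr_map(vol, reg, array(TRUE, c(3, 2, 1))),
               "does not match")
})

test_that("ROI means are unweighted, bounded and permutation-invariant", {
  map <- structure(
    list(cvr = array(c(0.1, 0.3, 0.2, NA), c(2, 2, 1)),
         mask = array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1)),
         n_voxels = 3L),
    class = "cvr_map"
  )
  expect_equal(roi_mean(map), mean(c(0.1, 0.3, 0.2)))
  sub <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(roi_mean(map, sub), 0.2)
  expect_gte(roi_mean(map), min(map$cvr, na.rm = TRUE))
  expect_lte(roi_mean(map), max(map$cvr, na.rm = TRUE))
  expect_error(roi_mean(map, array(FALSE, c(2, 2, 1))), "empty")
  expect_equal(hippocampal_average(0.21, 0.20), 0.205)
})

test_that("the 6 x MAD outlier rule matches hand computations", {
  x <- c(0.19, 0.20, 0.20, 0.21, 0.22, 1.0)
  # median 0.205, MAD 0.01, threshold 0.06
  expect_equal(mad_outliers(x), c(rep(FALSE, 5), TRUE))
  expect_equal(mad_outliers(rep(0.2, 5)), rep(FALSE, 5))
  expect_equal(mad_outliers(c(0, 0, 0, 0, 10)),
               c(rep(FALSE, 4), TRUE)) # MAD 0, strict inequality
  # invariance to adding a constant
  expect_equal(mad_outliers(x + 5), mad_outliers(x))
  expect_error(mad_outliers(c(1, 2)), "3 values")
  expect_error(mad_outliers(c(1, 2, NA)), "finite")
})

test_that("fit and map objects have tidy, glance and autoplot methods", {
  r <- make_reg(tau = 10)
  set.seed(1)
  y <- bold_series(r$reg$time, 5 * r$reg$normalized + rnorm(120, 0, 0.3),
                   units = "percent")
  fit <- fit_cvr_glm(y, r$reg, drift_order = 1)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 120)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_capno_trace(r$sim$trace, r$sim$truth,
                                   paradigm_spec()), "ggplot")
})
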