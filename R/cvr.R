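#' Convert a BOLD series to percent signal change
#'
#' \eqn{p(t) = 100 (s(t) - \bar s_{base}) / \bar s_{base}} where
#' \eqn{\bar s_{base}} is the mean signal over the normocapnic baseline
#' window. Applying the conversion to an already-percent series is an error.
#'
#' @param bold A [bold_series()] in raw units.
#' @param baseline_window Length-2 numeric, seconds (default `c(0, 60)`).
#' @return A [bold_series()] in percent units, with attribute
#'   `baseline_mean` (the raw baseline used).
#' @export
to_percent_change <- function(bold, baseline_window = c(0, 60)) {
  stopifnot(inherits(bold, "bold_series"))
  if (identical(bold_units(bold), "percent")) {
    abort("Series is already in percent-signal-change units.")
  }
  in_base <- bold$time >= baseline_window[1] & bold$time <= baseline_window[2]
  if (!any(in_base)) abort("Baseline window contains no samples.")
  b <- mean(bold$bold[in_base])
  if (b <= 0) abort("Baseline mean must be positive.")
  new_bold_series(bold$time, 100 * (bold$bold - b) / b, units = "percent",
                  repetition_time = attr(bold, "repetition_time"),
                  truth = attr(bold, "truth"), baseline_mean = b)
}

#' Fit the CVR general linear model
#'
#' Ordinary least squares of the BOLD series on an intercept, the normalized
#' EtCO2 regressor, and polynomial drift terms up to `drift_order`
#' (time and time squared, centred and scaled for conditioning). No
#' prewhitening is applied: with drift modelled, AR(1) noise affects only the
#' standard errors, not the unbiasedness of the point estimate.
#'
#' @param bold A [bold_series()] (raw or percent units).
#' @param reg A `cvr_regressor` from [build_regressor()] on the same grid.
#' @param drift_order 0, 1 or 2 polynomial drift terms (default 1).
#' @return A `cvr_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_cvr_glm <- function(bold, reg, drift_order = 1) {
  stopifnot(inherits(bold, "bold_series"), inherits(reg, "cvr_regressor"))
  if (nrow(bold) != nrow(reg) ||
      max(abs(bold$time - reg$time)) > 1e-8) {
    abort("BOLD series and regressor must share the same sample grid.")
  }
  if (!drift_order %in% 0:2) abort("`drift_order` must be 0, 1 or 2.")
  df <- tibble(y = bold$bold, regressor = reg$normalized)
  # drift columns are zero at t = 0 so the intercept stays the drift-free
  # baseline estimate; scaled by 100 s for conditioning only
  tc <- bold$time / 100
  form <- y ~ regressor
  if (drift_order >= 1) {
    df$drift1 <- tc
    form <- y ~ regressor + drift1
  }
  if (drift_order == 2) {
    df$drift2 <- tc^2
    form <- y ~ regressor + drift1 + drift2
  }
  fit <- lm(form, data = df)
  if (anyNA(coef(fit))) abort("Design matrix is rank deficient.")
  structure(
    list(
      model = fit,
      units = bold_units(bold),
      trace_max = attr(reg, "trace_max"),
      bulk_delay = attr(reg, "bulk_delay"),
      drift_order = drift_order,
      n = nrow(bold)
    ),
    class = "cvr_fit"
  )
}

#' @export
print.cvr_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  cat(sprintf(
    "<cvr_fit> (%s units, drift order %d, n = %d)\n  regressor beta = %.4g (SE %.3g, t = %.3g)\n",
    x$units, x$drift_order, x$n,
    s["regressor", 1], s["regressor", 2], s["regressor", 3]
  ))
  invisible(x)
}

#' Convert a fitted regressor coefficient to CVR in %BOLD/mmHg
#'
#' One mmHg of raw EtCO2 corresponds to `1/trace_max` units of the
#' normalized regressor, so CVR is the regressor coefficient divided by the
#' series maximum. For a fit on percent-change BOLD this is
#' `beta / trace_max`; for a fit on raw signal the coefficient is first
#' converted to percent units against the fitted intercept (the drift-free
#' baseline estimate): `100 * beta / (intercept * trace_max)`. Either route
#' equals the slope of a direct regression of percent-change BOLD on the raw
#' EtCO2 regressor in mmHg.
#'
#' @param fit A `cvr_fit` from [fit_cvr_glm()].
#' @param et Optional [etco2_series()] supplying the maximum; defaults to
#'   the maximum stored with the fit's regressor.
#' @return Scalar CVR, %BOLD per mmHg.
#' @export
cvr_from_fit <- function(fit, et = NULL) {
  stopifnot(inherits(fit, "cvr_fit"))
  mx <- if (is.null(et)) fit$trace_max else etco2_max(et)
  if (is.null(mx) || mx <= 0) abort("Trace maximum must be positive.")
  beta <- coef(fit$model)[["regressor"]]
  if (identical(fit$units, "percent")) {
    beta / mx
  } else {
    s0 <- coef(fit$model)[["(Intercept)"]]
    if (s0 <= 0) abort("Fitted baseline (intercept) must be positive.")
    100 * beta / (s0 * mx)
  }
}

#' Estimate CVR from a capnometry trace and a BOLD series
#'
#' The full single-ROI pipeline: end-tidal extraction, regressor
#' construction (with optional bulk-delay alignment), GLM fit on the raw
#' BOLD signal with polynomial drift, conversion of the coefficient to
#' %BOLD/mmHg against the fitted intercept, \eqn{\Delta}EtCO2 computation
#' and trace QC.
#'
#' @param trace A [capno_trace()].
#' @param bold A [bold_series()] in raw units.
#' @param paradigm A [paradigm_spec()].
#' @param drift_order Polynomial drift order (default 1).
#' @param delay `"none"` (default) or `"xcorr"` bulk-delay alignment.
#' @param min_breath_period,prominence_fraction Passed to
#'   [extract_end_tidal()].
#' @param max_delay,delay_step Passed to [build_regressor()].
#' @param slope_tolerance,baseline_tolerance Passed to [qc_trace()].
#' @return One-row tibble: `cvr` (%BOLD/mmHg), `delta_etco2` (mmHg), `beta`,
#'   `se`, `t`, `bulk_delay`, `qc_pass`, `n_breaths`, `n_volumes`.
#' @examples
#' sim <- simulate_capnometry(seed = 2)
#' bold <- simulate_bold(sim$truth, voxel_model(true_cvr = 0.25), seed = 2)
#' estimate_cvr(sim$trace, bold)
#' @export
estimate_cvr <- function(trace, bold, paradigm = paradigm_spec(),
                         drift_order = 1, delay = c("none", "xcorr"),
                         min_breath_period = 2, prominence_fraction = 0.1,
                         max_delay = 15, delay_step = 0.5,
                         slope_tolerance = 0.02, baseline_tolerance = 2) {
  delay <- match.arg(delay)
  et <- extract_end_tidal(trace, min_breath_period, prominence_fraction,
                          baseline_window = paradigm_baseline_window(paradigm))
  reg <- build_regressor(
    et, bold$time,
    bold_for_alignment = if (delay == "xcorr") bold else NULL,
    max_delay = max_delay, delay_step = delay_step
  )
  fit <- fit_cvr_glm(bold, reg, drift_order = drift_order)
  qc <- qc_trace(et, paradigm, slope_tolerance, baseline_tolerance)
  s <- summary(fit$model)$coefficients
  tibble(
    cvr = cvr_from_fit(fit),
    delta_etco2 = compute_delta_etco2(et, paradigm),
    beta = s["regressor", 1],
    se = s["regressor", 2],
    t = s["regressor", 3],
    bulk_delay = attr(reg, "bulk_delay"),
    qc_pass = qc_pass(qc),
    n_breaths = nrow(et),
    n_volumes = nrow(bold)
  )
}

#' Fit a voxelwise CVR map
#'
#' Applies [to_percent_change()], [fit_cvr_glm()] and [cvr_from_fit()]
#' independently to each voxel inside the mask of a small 4-D volume.
#'
#' @param bold_volume 4-D numeric array (x, y, z, time).
#' @param reg A `cvr_regressor` on the volume's time grid.
#' @param mask 3-D logical/0-1 array matching the spatial grid, with at
#'   least one true voxel.
#' @param drift_order Polynomial drift order (default 1).
#' @param baseline_window Seconds, for the percent conversion.
#' @return A `cvr_map`: list with `cvr` (3-D array, `NA` outside the mask),
#'   `mask`, and `n_voxels`.
#' @export
fit_cvr_map <- function(bold_volume, reg, mask, drift_order = 1,
                        baseline_window = c(0, 60)) {
  dims <- dim(bold_volume)
  if (length(dims) != 4) abort("`bold_volume` must be a 4-D array.")
  if (!identical(dim(mask), dims[1:3])) {
    abort("Mask grid does not match the volume grid.")
  }
  mask <- mask > 0
  if (!any(mask)) abort("Mask is empty.")
  times <- reg$time
  if (length(times) != dims[4]) {
    abort("Regressor length does not match the volume's time dimension.")
  }
  cvr <- array(NA_real_, dims[1:3])
  flat <- matrix(bold_volume, prod(dims[1:3]), dims[4])
  for (v in which(mask)) {
    series <- bold_series(times, flat[v, ], units = "raw")
    pct <- to_percent_change(series, baseline_window)
    fit <- fit_cvr_glm(pct, reg, drift_order)
    cvr[v] <- cvr_from_fit(fit)
  }
  structure(list(cvr = cvr, mask = mask, n_voxels = sum(mask)),
            class = "cvr_map")
}

#' @export
print.cvr_map <- function(x, ...) {
  cat(sprintf("<cvr_map> %s grid, %d voxels in mask, mean CVR %.3f %%/mmHg\n",
              paste(dim(x$cvr), collapse = "x"), x$n_voxels,
              mean(x$cvr[x$mask])))
  invisible(x)
}

#' Mean CVR over a region of interest
#'
#' Unweighted mean over masked voxels.
#'
#' @param map A `cvr_map` from [fit_cvr_map()].
#' @param mask Optional 3-D mask restricting further (defaults to the map's
#'   own mask); must be non-empty and match the grid.
#' @return Scalar mean CVR, %BOLD/mmHg.
#' @export
roi_mean <- function(map, mask = NULL) {
  stopifnot(inherits(map, "cvr_map"))
  m <- if (is.null(mask)) map$mask else mask > 0
  if (!identical(dim(m), dim(map$cvr))) {
    abort("Mask grid does not match the map grid.")
  }
  m <- m & map$mask
  if (!any(m)) abort("Mask is empty.")
  mean(map$cvr[m])
}

#' Bilateral hippocampal CVR
#'
#' Hippocampal CVR is defined as the simple average of the left and right
#' hippocampal ROI means.
#'
#' @param left,right Numeric CVR values (vectorized).
#' @return `(left + right) / 2`.
#' @examples
#' hippocampal_average(0.21, 0.20)
#' @export
hippocampal_average <- function(left, right) (left + right) / 2

#' Flag CVR outliers by the 6 x MAD rule
#'
#' A value is an outlier iff its absolute deviation from the median exceeds
#' `k` times the raw median absolute deviation (no normal-consistency
#' constant): `|x - median| > k * median(|x - median|)`. The inequality is
#' strict, so an all-equal input flags nothing.
#'
#' @param values Numeric vector of at least 3 finite values.
#' @param k Multiplier (default 6).
#' @return Logical vector of flags.
#' @examples
#' mad_outliers(c(0.19, 0.20, 0.20, 0.21, 0.22, 1.0))
#' @export
mad_outliers <- function(values, k = 6) {
  if (length(values) < 3) abort("At least 3 values are required.")
  if (!all(is.finite(values))) abort("All values must be finite.")
  med <- median(values)
  dev <- abs(values - med)
  dev > k * median(dev)
}
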