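#' Tidy a CVR GLM fit
#'
#' @param x A `cvr_fit` from [fit_cvr_glm()].
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble with one row per design column: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.cvr_fit <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$model)$coefficients
  ci <- confint(x$model, level = conf.level)
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' @rdname tidy.cvr_fit
#' @export
glance.cvr_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    cvr = cvr_from_fit(x),
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$model$df.residual,
    nobs = x$n,
    drift_order = x$drift_order,
    bulk_delay = x$bulk_delay %||% 0,
    units = x$units
  )
}

#' Tidy an association model fit
#'
#' @param x A `cvr_assoc` from [fit_association()].
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble of coefficients with confidence intervals and, when
#'   computed, the per-predictor Cohen's f^2.
#' @export
tidy.cvr_assoc <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$model)$coefficients
  ci <- confint(x$model, level = conf.level)
  out <- tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
  if (!is.null(x$f2_predictors)) {
    out <- left_join(out, x$f2_predictors, by = "term")
  }
  out
}

#' @rdname tidy.cvr_assoc
#' @export
glance.cvr_assoc <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    f2_overall = x$f2_overall,
    shapiro_w = x$shapiro_w,
    shapiro_p = x$shapiro_p,
    nobs = x$n
  )
}
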