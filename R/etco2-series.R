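#' Construct a breath-wise end-tidal CO2 series
#'
#' An `etco2_series` is a tibble with one row per breath (`time` in seconds,
#' `etco2` in mmHg, plus any extra columns) carrying the baseline window, the
#' baseline mean and the series maximum as attributes. These three quantities
#' drive regressor normalization: the regressor is
#' (x - baseline mean) / maximum.
#'
#' @param breaths Data frame with numeric columns `time` (strictly
#'   increasing, seconds) and `etco2` (mmHg).
#' @param baseline_window Length-2 numeric `(start, end)` seconds; breaths
#'   with `start <= time <= end` form the normocapnic baseline.
#' @return An `etco2_series` tibble.
#' @export
etco2_series <- function(breaths, baseline_window = c(0, 60)) {
  breaths <- as_tibble(breaths)
  if (!all(c("time", "etco2") %in% names(breaths))) {
    abort("`breaths` must have columns `time` and `etco2`.")
  }
  if (nrow(breaths) == 0) abort("`breaths` has no rows.")
  if (is.unsorted(breaths$time, strictly = TRUE)) {
    abort("Breath times must be strictly increasing.")
  }
  if (!all(is.finite(breaths$etco2))) abort("End-tidal values must be finite.")
  in_base <- breaths$time >= baseline_window[1] &
    breaths$time <= baseline_window[2]
  if (!any(in_base)) {
    abort("No breaths fall inside the baseline window.")
  }
  structure(
    breaths,
    baseline_window = as.numeric(baseline_window),
    baseline_mean = mean(breaths$etco2[in_base]),
    trace_max = max(breaths$etco2),
    class = c("etco2_series", class(breaths))
  )
}

#' @export
print.etco2_series <- function(x, ...) {
  cat(sprintf(
    "<etco2_series> %d breaths over %.1f s; baseline mean %.2f mmHg (window %.0f-%.0f s); max %.2f mmHg\n",
    nrow(x), diff(range(x$time)), attr(x, "baseline_mean"),
    attr(x, "baseline_window")[1], attr(x, "baseline_window")[2],
    attr(x, "trace_max")
  ))
  NextMethod()
}

#' Baseline mean, window and maximum of an end-tidal series
#' @param et An [etco2_series()].
#' @return `etco2_baseline_mean()` and `etco2_max()` return scalars (mmHg);
#'   `etco2_baseline_window()` a length-2 numeric (seconds).
#' @export
etco2_baseline_mean <- function(et) attr(et, "baseline_mean")

#' @rdname etco2_baseline_mean
#' @export
etco2_max <- function(et) attr(et, "trace_max")

#' @rdname etco2_baseline_mean
#' @export
etco2_baseline_window <- function(et) attr(et, "baseline_window")
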