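#' Extract breath-wise end-tidal CO2 values from a capnometry trace
#'
#' End-tidal CO2 is the maximum CO2 concentration at the end of each exhaled
#' breath. Breaths are detected as local maxima of the trace with a minimum
#' separation (`min_breath_period`) and a minimum topographic prominence
#' expressed as a fraction of the trace range. Flat plateaus are handled by
#' run-length compression; a plateau's time is its first sample, matching an
#' exhaustive per-breath `which.max` search.
#'
#' @param trace A [capno_trace()] (or data frame with `time`, `co2`).
#' @param min_breath_period Minimum separation between breaths, seconds
#'   (default 2, i.e. at most 30 breaths/min).
#' @param prominence_fraction Minimum peak prominence as a fraction of the
#'   trace range, in (0, 1) (default 0.1).
#' @param baseline_window Length-2 numeric, seconds; passed to
#'   [etco2_series()] (default `c(0, 60)`, the initial air block of the
#'   default paradigm).
#' @return An [etco2_series()] with one row per detected breath.
#' @examples
#' sim <- simulate_capnometry(seed = 1)
#' et <- extract_end_tidal(sim$trace)
#' all.equal(et$etco2, sim$truth$etco2)
#' @export
extract_end_tidal <- function(trace, min_breath_period = 2,
                              prominence_fraction = 0.1,
                              baseline_window = c(0, 60)) {
  trace <- as_tibble(trace)
  if (!all(c("time", "co2") %in% names(trace))) {
    abort("`trace` must have columns `time` and `co2`.")
  }
  if (!all(is.finite(trace$co2))) abort("Trace values must be finite.")
  if (diff(range(trace$time)) < 2 * min_breath_period) {
    abort("Trace must span at least two breaths.")
  }
  v <- trace$co2
  rng <- max(v) - min(v)
  if (rng == 0) abort("No breaths detected: trace is constant.")

  # run-length compress so flat plateaus count as one candidate
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) abort("No breaths detected.")
  interior <- 2:(k - 1)
  is_peak <- r$values[interior] > r$values[interior - 1] &
    r$values[interior] > r$values[interior + 1]
  cand <- starts[interior][is_peak]
  if (length(cand) == 0) abort("No breaths detected.")

  prom <- vapply(cand, peak_prominence, numeric(1), v = v)
  cand <- cand[prom >= prominence_fraction * rng]
  if (length(cand) == 0) {
    abort("No breaths detected: no peak exceeds the prominence threshold.")
  }

  # enforce minimum breath separation, keeping higher peaks first
  ord <- order(-v[cand], trace$time[cand])
  kept_t <- numeric(0)
  kept <- integer(0)
  for (i in cand[ord]) {
    ti <- trace$time[i]
    if (all(abs(ti - kept_t) >= min_breath_period)) {
      kept <- c(kept, i)
      kept_t <- c(kept_t, ti)
    }
  }
  kept <- sort(kept)
  etco2_series(
    tibble(time = trace$time[kept], etco2 = v[kept]),
    baseline_window = baseline_window
  )
}

# topographic prominence of the peak at index i: height above the higher of
# the two minima separating it from the nearest strictly higher samples
peak_prominence <- function(i, v) {
  pv <- v[i]
  higher_l <- which(v[seq_len(i - 1)] > pv)
  left_base <- if (length(higher_l)) {
    min(v[(max(higher_l) + 1):i])
  } else {
    min(v[seq_len(i)])
  }
  right <- v[i:length(v)]
  higher_r <- which(right > pv)
  right_base <- if (length(higher_r)) {
    min(right[seq_len(min(higher_r))])
  } else {
    min(right)
  }
  pv - max(left_base, right_base)
}

#' Build a model regressor from an end-tidal series
#'
#' Interpolates the breath-wise end-tidal envelope piecewise-linearly onto
#' the BOLD sampling grid, optionally estimates a bulk haemodynamic delay by
#' cross-correlation against a BOLD series, and normalizes by subtracting the
#' baseline-window mean and dividing by the maximum (see
#' [normalize_etco2()]).
#'
#' @param et An [etco2_series()].
#' @param sample_times Numeric BOLD sample times (seconds), or an
#'   [acquisition_spec()].
#' @param bold_for_alignment Optional [bold_series()] on the same grid; if
#'   supplied, the bulk delay is the argmax of the normalized
#'   cross-correlation over `seq(0, max_delay, delay_step)`. Default `NULL`
#'   (delay 0).
#' @param max_delay,delay_step Delay search grid, seconds (defaults 15, 0.5).
#' @return A `cvr_regressor` tibble (`time`, `raw_mmHg`, `normalized`) with
#'   attributes `bulk_delay`, `baseline_mean`, `trace_max` and
#'   `baseline_window`.
#' @export
build_regressor <- function(et, sample_times, bold_for_alignment = NULL,
                            max_delay = 15, delay_step = 0.5) {
  stopifnot(inherits(et, "etco2_series"))
  if (inherits(sample_times, "acquisition_spec")) {
    sample_times <- acquisition_times(sample_times)
  }
  gap <- if (nrow(et) > 1) median(diff(et$time)) else Inf
  if (min(sample_times) < min(et$time) - gap ||
      max(sample_times) > max(et$time) + gap) {
    abort("Acquisition window lies outside the end-tidal series support.")
  }

  delay <- 0
  if (!is.null(bold_for_alignment)) {
    grid <- seq(0, max_delay, by = delay_step)
    score <- vapply(grid, function(d) {
      x <- approx(et$time, et$etco2, xout = sample_times - d, rule = 2)$y
      suppressWarnings(stats::cor(x, bold_for_alignment$bold))
    }, numeric(1))
    delay <- grid[which.max(score)]
  }

  raw <- approx(et$time, et$etco2, xout = sample_times - delay, rule = 2)$y
  bw <- etco2_baseline_window(et)
  # centre on the breath-wise baseline mean (interpolation onto the sample
  # grid smears the block boundary, so the sample mean over the window would
  # be contaminated by the first transition)
  norm <- normalize_etco2(raw, sample_times, baseline_window = bw,
                          baseline_mean = etco2_baseline_mean(et))
  structure(
    tibble(time = sample_times, raw_mmHg = raw, normalized = as.numeric(norm)),
    bulk_delay = delay,
    baseline_mean = attr(norm, "baseline_mean"),
    trace_max = attr(norm, "trace_max"),
    baseline_window = bw,
    class = c("cvr_regressor", "tbl_df", "tbl", "data.frame")
  )
}

#' Normalize an end-tidal CO2 time course
#'
#' The normalized regressor is the raw interpolated EtCO2 minus its
#' baseline-window mean, divided by its global maximum:
#' \deqn{n(t) = (x(t) - \bar x_{base}) / \max_t x(t).}
#' The result is dimensionless, zero-mean over the baseline, and invariant
#' to positive rescaling of the raw trace.
#'
#' @param values Raw interpolated EtCO2 values, mmHg.
#' @param times Sample times, seconds (same length as `values`).
#' @param baseline_window Length-2 numeric `(start, end)` seconds.
#' @param baseline_mean Optional pre-computed baseline mean (mmHg), e.g. the
#'   breath-wise mean of an [etco2_series()]; by default the mean of
#'   `values` over the baseline window.
#' @return Numeric vector with attributes `baseline_mean` and `trace_max`.
#' @examples
#' normalize_etco2(c(40, 40, 48, 48), 1:4, c(1, 2))
#' @export
normalize_etco2 <- function(values, times = seq_along(values),
                            baseline_window, baseline_mean = NULL) {
  if (length(values) != length(times)) {
    abort("`values` and `times` lengths differ.")
  }
  if (is.null(baseline_mean)) {
    in_base <- times >= baseline_window[1] & times <= baseline_window[2]
    if (!any(in_base)) abort("Baseline window contains no samples.")
    baseline_mean <- mean(values[in_base])
  }
  mx <- max(values)
  if (mx <= 0) abort("Trace maximum must be positive to normalize.")
  out <- (values - baseline_mean) / mx
  attr(out, "baseline_mean") <- baseline_mean
  attr(out, "trace_max") <- mx
  out
}

#' Hypercapnic EtCO2 increase over baseline
#'
#' \eqn{\Delta}EtCO2 is the mean end-tidal CO2 achieved during hypercapnia
#' minus the initial normocapnic level. The hypercapnic level is computed per
#' CO2 block from breaths in its second half (the half-open interval
#' (midpoint, end], where the level has stabilised), then averaged across
#' blocks; the normocapnic level is the mean over breaths in the initial air
#' block.
#'
#' @param et An [etco2_series()].
#' @param paradigm A [paradigm_spec()] with at least one CO2 block.
#' @return Scalar \eqn{\Delta}EtCO2, mmHg.
#' @export
compute_delta_etco2 <- function(et, paradigm = paradigm_spec()) {
  stopifnot(inherits(et, "etco2_series"))
  co2_blocks <- which(paradigm$gas == "co2")
  if (length(co2_blocks) == 0) abort("Paradigm has no CO2 block.")
  base <- block_breaths(et, paradigm$start[1], paradigm$end[1],
                        closed_left = TRUE)
  if (length(base) == 0) abort("No breaths in the initial air block.")
  block_means <- vapply(co2_blocks, function(b) {
    idx <- block_breaths(et, paradigm$midpoint[b], paradigm$end[b])
    if (length(idx) == 0) {
      abort(sprintf("No breaths in the second half of CO2 block %d.", b))
    }
    mean(et$etco2[idx])
  }, numeric(1))
  mean(block_means) - mean(et$etco2[base])
}

# breaths with time in (start, end]; closed_left makes it [start, end]
block_breaths <- function(et, start, end, closed_left = FALSE) {
  lower <- if (closed_left) et$time >= start else et$time > start
  which(lower & et$time <= end)
}

#' Quality control of an end-tidal trace against its paradigm
#'
#' Codifies the visual checks applied to capnometry traces: EtCO2 must reach
#' a steady state within each CO2 block (absolute least-squares slope of the
#' second-half breath values below `slope_tolerance`), and the baseline after
#' each CO2 block must return to the initial normocapnic level (absolute
#' deviation of the post-block air-period mean below `baseline_tolerance`).
#'
#' @param et An [etco2_series()].
#' @param paradigm A [paradigm_spec()].
#' @param slope_tolerance mmHg/s (default 0.02).
#' @param baseline_tolerance mmHg (default 2).
#' @return A `qc_report` tibble (`check`, `block`, `statistic`, `tolerance`,
#'   `pass`) with attribute `overall_pass`; see [qc_pass()].
#' @export
qc_trace <- function(et, paradigm = paradigm_spec(), slope_tolerance = 0.02,
                     baseline_tolerance = 2) {
  stopifnot(inherits(et, "etco2_series"))
  base <- block_breaths(et, paradigm$start[1], paradigm$end[1],
                        closed_left = TRUE)
  if (length(base) == 0) abort("No breaths in the initial air block.")
  base_mean <- mean(et$etco2[base])

  rows <- list()
  for (b in which(paradigm$gas == "co2")) {
    idx <- block_breaths(et, paradigm$midpoint[b], paradigm$end[b])
    if (length(idx) < 2) {
      abort(sprintf("Fewer than two breaths in the second half of CO2 block %d.", b))
    }
    tt <- et$time[idx]; yy <- et$etco2[idx]
    slope <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
    rows[[length(rows) + 1]] <- tibble(
      check = "steady_state", block = b, statistic = slope,
      tolerance = slope_tolerance, pass = abs(slope) <= slope_tolerance
    )
    if (b < nrow(paradigm) && paradigm$gas[b + 1] == "air") {
      aidx <- block_breaths(et, paradigm$start[b + 1], paradigm$end[b + 1])
      if (length(aidx) == 0) {
        abort(sprintf("No breaths in the air block after CO2 block %d.", b))
      }
      dev <- mean(et$etco2[aidx]) - base_mean
      rows[[length(rows) + 1]] <- tibble(
        check = "baseline_return", block = b + 1, statistic = dev,
        tolerance = baseline_tolerance, pass = abs(dev) <= baseline_tolerance
      )
    }
  }
  out <- bind_rows(rows)
  structure(out, overall_pass = all(out$pass),
            class = c("qc_report", class(out)))
}

#' Overall pass flag of a QC report
#' @param report A `qc_report` from [qc_trace()].
#' @return Logical scalar: conjunction of all per-block flags.
#' @export
qc_pass <- function(report) attr(report, "overall_pass")

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> overall %s\n",
              if (qc_pass(x)) "PASS" else "FAIL"))
  NextMethod()
}
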