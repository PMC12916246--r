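#' Simulate a BOLD series driven by an end-tidal CO2 time course
#'
#' Forward model: the BOLD signal is the baseline scaled by the CVR response
#' to the end-tidal CO2 excursion, plus polynomial drift and stationary AR(1)
#' noise,
#' \deqn{s(t) = s_0 (1 + \mathrm{CVR} (e(t) - \bar e_{base}) / 100)
#'   + d_1 t + d_2 t^2 + \epsilon(t),}
#' where \eqn{e(t)} is the piecewise-linear interpolation of the breath-wise
#' end-tidal series and \eqn{\bar e_{base}} its baseline-window mean. The
#' noise is AR(1) with lag-1 autocorrelation `ar1_coefficient` and marginal
#' standard deviation `noise_sd`.
#'
#' @param truth An [etco2_series()] covering the acquisition window.
#' @param vox A [voxel_model()].
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the noise stream.
#' @return A `bold_series` tibble (`time` s, `bold` signal units) with
#'   attributes `units = "raw"`, `repetition_time` and `truth` (the voxel
#'   model, for recovery tests).
#' @export
simulate_bold <- function(truth, vox = voxel_model(),
                          acq = acquisition_spec(), seed = 1L) {
  stopifnot(inherits(truth, "etco2_series"), inherits(vox, "voxel_model"),
            inherits(acq, "acquisition_spec"))
  times <- acquisition_times(acq)
  gap <- median(diff(truth$time))
  if (max(times) > max(truth$time) + gap) {
    abort(sprintf(
      "Acquisition (%.1f s) extends beyond the end-tidal series support (%.1f s).",
      max(times), max(truth$time)
    ))
  }
  e <- approx(truth$time, truth$etco2, xout = times, rule = 2)$y
  m <- etco2_baseline_mean(truth)
  noise <- ar1_noise(length(times), vox$noise_sd, vox$ar1_coefficient, seed)
  signal <- vox$s0 * (1 + vox$true_cvr * (e - m) / 100) +
    vox$drift_linear * times + vox$drift_quadratic * times^2 + noise
  new_bold_series(times, signal, units = "raw",
                  repetition_time = acq$repetition_time, truth = vox)
}

#' Simulate a small 4-D BOLD volume of independent voxels
#'
#' Applies [simulate_bold()] voxelwise with a per-voxel ground-truth CVR
#' array; voxels share `s0`, drift and noise parameters but draw independent
#' noise.
#'
#' @param truth An [etco2_series()].
#' @param cvr_array 3-D numeric array of ground-truth CVR (%BOLD/mmHg).
#' @param acq An [acquisition_spec()] (its `grid_shape` is ignored in favour
#'   of `dim(cvr_array)`).
#' @param vox A [voxel_model()] supplying the shared parameters; its
#'   `true_cvr` is ignored.
#' @param seed Integer seed; voxel v uses sub-stream `seed + v`.
#' @return 4-D array `c(dim(cvr_array), n_volumes)` with attributes
#'   `truth_cvr` and `times`.
#' @export
simulate_bold_volume <- function(truth, cvr_array, acq = acquisition_spec(),
                                 vox = voxel_model(), seed = 1L) {
  stopifnot(length(dim(cvr_array)) == 3)
  dims <- dim(cvr_array)
  out <- array(NA_real_, c(dims, acq$n_volumes))
  flat <- matrix(NA_real_, prod(dims), acq$n_volumes)
  for (v in seq_len(prod(dims))) {
    vm <- vox
    vm$true_cvr <- cvr_array[v]
    flat[v, ] <- simulate_bold(truth, vm, acq, seed = seed + v)$bold
  }
  out[] <- flat
  attr(out, "truth_cvr") <- cvr_array
  attr(out, "times") <- acquisition_times(acq)
  out
}

# stationary AR(1) noise with marginal sd `sd` and lag-1 autocorrelation `phi`
ar1_noise <- function(n, sd, phi, seed) {
  if (sd == 0) return(numeric(n))
  withr::with_seed(seed, {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd)
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + innov[i]
    x
  })
}

new_bold_series <- function(time, bold, units, repetition_time = NULL,
                            truth = NULL, baseline_mean = NULL) {
  structure(
    tibble(time = time, bold = bold),
    units = units,
    repetition_time = repetition_time,
    truth = truth,
    baseline_mean = baseline_mean,
    class = c("bold_series", "tbl_df", "tbl", "data.frame")
  )
}

#' Construct a BOLD ROI-mean series
#'
#' @param time Sample times, seconds.
#' @param bold Signal values (arbitrary units, or percent signal change).
#' @param units `"raw"` or `"percent"`.
#' @return A `bold_series` tibble.
#' @export
bold_series <- function(time, bold, units = "raw") {
  if (length(time) != length(bold)) abort("`time` and `bold` lengths differ.")
  if (!all(is.finite(bold))) abort("`bold` must be finite.")
  units <- match.arg(units, c("raw", "percent"))
  new_bold_series(time, bold, units = units)
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d volumes over %.1f s (%s units)\n",
              nrow(x), diff(range(x$time)), attr(x, "units")))
  NextMethod()
}

#' Units flag of a BOLD series
#' @param bold A [bold_series()].
#' @return `"raw"` or `"percent"`.
#' @export
bold_units <- function(bold) attr(bold, "units")
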