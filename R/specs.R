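#' Gas-delivery paradigm for the CO2 challenge
#'
#' Describes the block structure of the hypercapnia paradigm as a sequence of
#' gas states and durations. The default is the block design used for older
#' cohorts: 60 s of medical air, then two 75 s blocks of 5% CO2 in air, each
#' followed by 75 s of air. The first block must be air: it defines the
#' normocapnic baseline window used for regressor normalization and for the
#' denominator of \eqn{\Delta}EtCO2.
#'
#' @param blocks A data frame with columns `gas` (`"air"` or `"co2"`) and
#'   `duration` (seconds). Defaults to the 60/75/75/75/75 design.
#' @return A `paradigm_spec` tibble with columns `gas`, `duration`, `start`,
#'   `end` and `midpoint` (seconds from scan start).
#' @examples
#' paradigm_spec()
#' @export
paradigm_spec <- function(blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- tibble(
      gas = c("air", "co2", "air", "co2", "air"),
      duration = c(60, 75, 75, 75, 75)
    )
  }
  blocks <- as_tibble(blocks)
  if (!all(c("gas", "duration") %in% names(blocks))) {
    abort("`blocks` must have columns `gas` and `duration`.")
  }
  if (!all(blocks$gas %in% c("air", "co2"))) {
    abort("`gas` must be \"air\" or \"co2\".")
  }
  if (!all(is.finite(blocks$duration)) || any(blocks$duration <= 0)) {
    abort("Block durations must be positive and finite.")
  }
  if (blocks$gas[1] != "air") {
    abort("The first block must be air: it defines the normocapnic baseline.")
  }
  blocks$end <- cumsum(blocks$duration)
  blocks$start <- blocks$end - blocks$duration
  blocks$midpoint <- (blocks$start + blocks$end) / 2
  structure(blocks[, c("gas", "duration", "start", "end", "midpoint")],
            class = c("paradigm_spec", class(blocks)))
}

#' Total duration of a paradigm in seconds
#' @param paradigm A [paradigm_spec()].
#' @return Scalar duration in seconds.
#' @export
paradigm_duration <- function(paradigm) {
  sum(paradigm$duration)
}

#' Baseline (initial normocapnic) window of a paradigm
#' @param paradigm A [paradigm_spec()].
#' @return Length-2 numeric `(start, end)` of the first air block, seconds.
#' @export
paradigm_baseline_window <- function(paradigm) {
  c(paradigm$start[1], paradigm$end[1])
}

#' Breath-by-breath capnometry model
#'
#' Parameterizes the synthetic capnogram: a train of breaths whose waveform is
#' a raised-cosine rise from the inspiratory floor to a flat end-tidal plateau
#' and a raised-cosine fall back. The per-breath plateau tracks the block
#' target (baseline, plus the hypercapnic boost during CO2 blocks) through a
#' first-order exponential wash-in with the given time constant.
#'
#' @param breathing_rate Breaths per minute (default 12, a typical resting
#'   adult rate).
#' @param baseline_etco2 Normocapnic end-tidal CO2, mmHg (default 40).
#' @param hypercapnic_boost Rise in end-tidal CO2 under 5% CO2, mmHg
#'   (default 8, a conventional response to this inspired fraction).
#' @param transition_time_constant Wash-in/out time constant, seconds
#'   (default 10). Zero gives instantaneous block transitions.
#' @param inspiratory_floor CO2 partial pressure during inspiration, mmHg
#'   (default 2; re-breathing keeps it slightly above zero).
#' @param sampling_rate Capnometer sampling rate, Hz (default 20). Must give
#'   at least 4 samples per breath.
#' @param plateau_fraction Fraction of each breath occupied by the flat
#'   end-tidal plateau, in (0, 1) (default 0.3).
#' @param plateau_noise_sd Breath-to-breath jitter of the plateau value, mmHg
#'   (default 0, i.e. noiseless plateaus).
#' @return A `breath_model` list.
#' @export
breath_model <- function(breathing_rate = 12,
                         baseline_etco2 = 40,
                         hypercapnic_boost = 8,
                         transition_time_constant = 10,
                         inspiratory_floor = 2,
                         sampling_rate = 20,
                         plateau_fraction = 0.3,
                         plateau_noise_sd = 0) {
  if (inspiratory_floor < 0) abort("`inspiratory_floor` must be >= 0.")
  if (baseline_etco2 <= inspiratory_floor) {
    abort("`baseline_etco2` must exceed `inspiratory_floor`.")
  }
  if (hypercapnic_boost < 0) abort("`hypercapnic_boost` must be >= 0.")
  if (transition_time_constant < 0) {
    abort("`transition_time_constant` must be >= 0.")
  }
  if (breathing_rate <= 0) abort("`breathing_rate` must be positive.")
  if (plateau_fraction <= 0 || plateau_fraction >= 1) {
    abort("`plateau_fraction` must be in (0, 1).")
  }
  if (plateau_noise_sd < 0) abort("`plateau_noise_sd` must be >= 0.")
  min_rate <- 4 * breathing_rate / 60
  if (sampling_rate < min_rate) {
    abort(sprintf(
      "`sampling_rate` (%.3g Hz) cannot resolve breaths at %.3g/min; at least %.3g Hz (4 samples per breath) is required.",
      sampling_rate, breathing_rate, min_rate
    ))
  }
  structure(
    list(
      breathing_rate = breathing_rate,
      baseline_etco2 = baseline_etco2,
      hypercapnic_boost = hypercapnic_boost,
      transition_time_constant = transition_time_constant,
      inspiratory_floor = inspiratory_floor,
      sampling_rate = sampling_rate,
      plateau_fraction = plateau_fraction,
      plateau_noise_sd = plateau_noise_sd
    ),
    class = "breath_model"
  )
}

#' BOLD acquisition grid
#'
#' @param repetition_time TR in seconds (default 3).
#' @param n_volumes Number of volumes (default 120, covering the default
#'   360 s paradigm).
#' @param grid_shape Integer voxel dimensions for volume mode; `c(1, 1, 1)`
#'   (the default) denotes a single ROI-mean series.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(repetition_time = 3, n_volumes = 120,
                             grid_shape = c(1L, 1L, 1L)) {
  if (repetition_time <= 0) abort("`repetition_time` must be positive.")
  if (n_volumes < 2) abort("`n_volumes` must be at least 2.")
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers.")
  }
  structure(
    list(
      repetition_time = repetition_time,
      n_volumes = as.integer(n_volumes),
      grid_shape = as.integer(grid_shape)
    ),
    class = "acquisition_spec"
  )
}

#' Sample times of an acquisition
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of volume acquisition times, seconds.
#' @export
acquisition_times <- function(acq) {
  (seq_len(acq$n_volumes) - 1) * acq$repetition_time
}

#' Single-voxel BOLD forward model
#'
#' @param s0 Baseline signal, arbitrary units (> 0; default 500).
#' @param true_cvr Ground-truth CVR, %BOLD per mmHg (default 0.2, the order of
#'   hippocampal grey-matter values).
#' @param drift_linear Linear drift, signal units per second (default 0).
#' @param drift_quadratic Quadratic drift, units per second squared (default 0).
#' @param noise_sd Marginal standard deviation of the AR(1) noise, signal
#'   units (default 0).
#' @param ar1_coefficient Lag-1 autocorrelation of the noise, in `[0, 1)`
#'   (default 0).
#' @return A `voxel_model` list.
#' @export
voxel_model <- function(s0 = 500, true_cvr = 0.2, drift_linear = 0,
                        drift_quadratic = 0, noise_sd = 0,
                        ar1_coefficient = 0) {
  if (s0 <= 0) abort("`s0` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    abort("`ar1_coefficient` must be in [0, 1).")
  }
  structure(
    list(
      s0 = s0, true_cvr = true_cvr, drift_linear = drift_linear,
      drift_quadratic = drift_quadratic, noise_sd = noise_sd,
      ar1_coefficient = ar1_coefficient
    ),
    class = "voxel_model"
  )
}
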