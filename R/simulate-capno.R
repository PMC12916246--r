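#' Simulate a capnometry trace for a gas paradigm
#'
#' Generates a sampled CO2 partial-pressure trace from the face-mask line
#' together with the ground-truth breath-wise end-tidal series. Each breath is
#' a raised-cosine rise from the inspiratory floor to a flat end-tidal
#' plateau, then a raised-cosine fall; the plateau value relaxes toward the
#' current block target (baseline, plus the hypercapnic boost in CO2 blocks)
#' with the model's first-order time constant. Ground-truth breath times are
#' aligned to the sampling grid at the first sample of each plateau, so an
#' exhaustive per-breath maximum search over the trace recovers the truth
#' exactly.
#'
#' @param paradigm A [paradigm_spec()].
#' @param breath A [breath_model()].
#' @param seed Integer seed; fixes all randomness (plateau jitter).
#' @return A list of class `capno_sim` with elements
#'   \describe{
#'     \item{trace}{`capno_trace` tibble (`time` s, `co2` mmHg) with a
#'       `sampling_rate` attribute.}
#'     \item{truth}{[etco2_series()] of ground-truth plateau times/values with
#'       extra columns `breath` and `gas`.}
#'   }
#' @examples
#' sim <- simulate_capnometry(paradigm_spec(), breath_model(), seed = 1)
#' head(sim$truth)
#' @export
simulate_capnometry <- function(paradigm = paradigm_spec(),
                                breath = breath_model(),
                                seed = 1L) {
  stopifnot(inherits(paradigm, "paradigm_spec"), inherits(breath, "breath_model"))
  fs <- breath$sampling_rate
  total <- paradigm_duration(paradigm)
  t_breath <- 60 / breath$breathing_rate
  n_breaths <- floor(total / t_breath + 1e-9)
  if (n_breaths < 2) abort("Paradigm too short to contain two breaths.")

  p <- breath$plateau_fraction
  rise <- (1 - p) * t_breath / 2
  fall <- rise
  plat_len <- p * t_breath
  starts <- (seq_len(n_breaths) - 1) * t_breath
  plat_start <- starts + rise
  plat_mid <- plat_start + plat_len / 2

  # block target at each breath's plateau midpoint
  block_of <- findInterval(plat_mid, paradigm$start, rightmost.closed = TRUE)
  target <- breath$baseline_etco2 +
    ifelse(paradigm$gas[block_of] == "co2", breath$hypercapnic_boost, 0)

  # first-order relaxation of plateau values toward the block target
  tau <- breath$transition_time_constant
  v <- numeric(n_breaths)
  prev <- breath$baseline_etco2
  decay <- if (tau > 0) exp(-t_breath / tau) else 0
  for (k in seq_len(n_breaths)) {
    v[k] <- target[k] + (prev - target[k]) * decay
    prev <- v[k]
  }
  if (breath$plateau_noise_sd > 0) {
    v <- withr::with_seed(seed, v + rnorm(n_breaths, 0, breath$plateau_noise_sd))
    v <- pmax(v, breath$inspiratory_floor + 0.5)
  }

  # sample grid and waveform; plateau samples are exactly v[k]
  n_samp <- floor(total * fs + 1e-9)
  times <- (seq_len(n_samp) - 1) / fs
  k <- pmin(floor(times / t_breath) + 1, n_breaths)
  local <- times - starts[k]
  amp <- v[k] - breath$inspiratory_floor
  co2 <- numeric(n_samp)
  in_rise <- local < rise
  in_plat <- !in_rise & local < rise + plat_len
  in_fall <- !in_rise & !in_plat
  co2[in_rise] <- breath$inspiratory_floor +
    amp[in_rise] * (1 - cos(pi * local[in_rise] / rise)) / 2
  co2[in_plat] <- v[k[in_plat]]
  co2[in_fall] <- breath$inspiratory_floor +
    amp[in_fall] * (1 + cos(pi * (local[in_fall] - rise - plat_len) / fall)) / 2

  # truth time = first grid sample inside each plateau
  truth_time <- ceiling(plat_start * fs - 1e-9) / fs
  truth <- tibble(
    breath = seq_len(n_breaths),
    time = truth_time,
    etco2 = v,
    gas = paradigm$gas[block_of]
  )

  trace <- structure(
    tibble(time = times, co2 = co2),
    sampling_rate = fs,
    class = c("capno_trace", "tbl_df", "tbl", "data.frame")
  )
  structure(
    list(
      trace = trace,
      truth = etco2_series(truth, paradigm_baseline_window(paradigm))
    ),
    class = "capno_sim"
  )
}

#' @export
print.capno_sim <- function(x, ...) {
  cat(sprintf(
    "<capno_sim> %.0f s trace at %g Hz, %d breaths\n",
    max(x$trace$time), attr(x$trace, "sampling_rate"), nrow(x$truth)
  ))
  invisible(x)
}

#' Construct a capnometry trace object
#'
#' @param time Sample times, seconds, strictly increasing.
#' @param co2 CO2 partial pressure, mmHg, finite and non-negative.
#' @param sampling_rate Hz; inferred from the median time step if `NULL`.
#' @return A `capno_trace` tibble.
#' @export
capno_trace <- function(time, co2, sampling_rate = NULL) {
  if (length(time) != length(co2)) abort("`time` and `co2` lengths differ.")
  if (is.unsorted(time, strictly = TRUE)) {
    abort("`time` must be strictly increasing.")
  }
  if (!all(is.finite(co2)) || any(co2 < 0)) {
    abort("`co2` must be finite and non-negative.")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / median(diff(time))
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  structure(
    tibble(time = time, co2 = co2),
    sampling_rate = sampling_rate,
    class = c("capno_trace", "tbl_df", "tbl", "data.frame")
  )
}
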