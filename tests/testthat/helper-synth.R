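# shared fixtures, all generated in code

quick_sim <- function(tau = 0, seed = 1, boost = 8, plateau_noise = 0,
                      rate = 12, fs = 20, baseline = 40) {
  simulate_capnometry(
    paradigm_spec(),
    breath_model(breathing_rate = rate, baseline_etco2 = baseline,
                 hypercapnic_boost = boost,
                 transition_time_constant = tau,
                 plateau_noise_sd = plateau_noise, sampling_rate = fs),
    seed = seed
  )
}

# exhaustive per-breath maximum search over fixed breath windows
oracle_breath_maxima <- function(trace, period) {
  k <- floor(trace$time / period + 1e-9)
  rows <- lapply(split(seq_len(nrow(trace)), k), function(idx) {
    i <- idx[which.max(trace$co2[idx])]
    c(time = trace$time[i], etco2 = trace$co2[i])
  })
  m <- do.call(rbind, rows)
  tibble::tibble(time = unname(m[, "time"]), etco2 = unname(m[, "etco2"]))
}

# manual etco2_series from breath times/values
manual_et <- function(time, etco2, baseline_window = c(0, 60)) {
  etco2_series(tibble::tibble(time = time, etco2 = etco2), baseline_window)
}

# brute-force Benjamini-Hochberg step-up rejection at level q:
# find the largest i with p_(i) <= (i/m) q, reject the i smallest p
bf_stepup_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  s <- p[o]
  k <- max(c(0L, which(s <= seq_len(m) / m * q)))
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# a noise-free cohort spec: all latent/change/measurement noise off,
# identity scanners, zero base rates
noiseless_cohort_spec <- function(...) {
  m <- default_metric_table()
  m$sd <- 0
  m$change_sd <- 0
  m$noise_sd <- 0
  m$annual_change <- 0
  cohort_spec(metrics = m, lr_jitter_sd = 0, whole_brain_jitter_sd = 0,
              scanner_scale = c(1, 1), scanner_offset_frac = c(0, 0), ...)
}

# apply a random positive-scale affine scanner transform to wave-2 values,
# with the additive offset scaled to each metric's magnitude
affine_wave2 <- function(m, scale, offset_rel) {
  m |>
    dplyr::group_by(metric) |>
    dplyr::mutate(value = ifelse(wave == 2,
                                 scale * value + offset_rel * mean(abs(value)),
                                 value)) |>
    dplyr::ungroup()
}

# joined wave-2 analysis frame for direct fit_association calls
wave2_frame <- function(cohort) {
  wide <- tidyr::pivot_wider(
    dplyr::filter(cohort$measurements, wave == 2),
    id_cols = "participant", names_from = "metric", values_from = "value"
  )
  dplyr::left_join(cohort$participants, wide, by = "participant")
}
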