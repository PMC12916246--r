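#' Z-score a metric within one wave
#'
#' Standardization with the sample (n-1) standard deviation, as in the base
#' `scale()` function: z = (x - mean) / sd. Applied within each imaging wave
#' separately, this removes any positive-scale affine scanner effect, which
#' is what makes cross-scanner change scores comparable.
#'
#' @param values Numeric vector (one value per participant) with at least 2
#'   elements and non-zero variance.
#' @return Numeric z-scores.
#' @examples
#' zscore_wave(c(1, 2, 3))
#' @export
zscore_wave <- function(values) {
  if (length(values) < 2) abort("At least 2 participants are required.")
  if (!all(is.finite(values))) abort("Values must be finite.")
  s <- sd(values)
  if (s == 0) abort("Zero variance: cannot z-score.")
  (values - mean(values)) / s
}

# decline orientation by metric family: volumes and FA decline downward,
# diffusivities upward
decline_direction <- function(metric) {
  family <- sub("_.*$", "", metric)
  dplyr::case_when(
    family %in% c("gmv", "fa") ~ "negative",
    family %in% c("md", "rd", "l1") ~ "positive",
    TRUE ~ NA_character_
  )
}

#' Standardized two-wave change scores
#'
#' For each metric, z-scores the values within each wave across participants
#' and takes delta = z(wave 2) - z(wave 1). Deltas are relative measures:
#' they capture how much a participant changed compared to the rest of the
#' cohort, not absolute change, and are invariant to positive-scale affine
#' scanner differences between waves. Each metric carries a decline
#' orientation: for volumes and FA more negative delta means more decline;
#' for MD/RD/L1 more positive delta means more decline.
#'
#' @param measurements Long tibble with columns `participant`, `wave`
#'   (1/2), `metric`, `value`, e.g. the `measurements` element of
#'   [simulate_cohort()].
#' @param metrics Optional character vector restricting the metrics.
#' @param incomplete `"drop"` (default) silently analyses completers only,
#'   reporting the dropped count via a message; `"error"` aborts listing the
#'   participants missing a wave.
#' @return Tibble: `participant`, `metric`, `z_wave1`, `z_wave2`, `delta`,
#'   `decline_direction`.
#' @export
compute_change_scores <- function(measurements, metrics = NULL,
                                  incomplete = c("drop", "error")) {
  incomplete <- match.arg(incomplete)
  need <- c("participant", "wave", "metric", "value")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", toString(missing_cols)))
  }
  d <- as_tibble(measurements)
  if (!is.null(metrics)) d <- filter(d, .data$metric %in% metrics)
  if (!all(d$wave %in% c(1, 2))) abort("`wave` must be 1 or 2.")

  wide <- tidyr::pivot_wider(d, names_from = "wave", values_from = "value",
                             names_prefix = "w")
  bad <- unique(wide$participant[is.na(wide$w1) | is.na(wide$w2)])
  if (length(bad)) {
    if (incomplete == "error") {
      abort(paste0("Participants missing a wave: ", toString(bad)))
    }
    inform(sprintf("Dropping %d participant(s) without both waves.",
                   length(bad)))
    wide <- filter(wide, !.data$participant %in% bad)
  }
  wide |>
    group_by(.data$metric) |>
    mutate(z_wave1 = zscore_wave(.data$w1),
           z_wave2 = zscore_wave(.data$w2)) |>
    ungroup() |>
    mutate(delta = .data$z_wave2 - .data$z_wave1,
           decline_direction = decline_direction(.data$metric)) |>
    select("participant", "metric", "z_wave1", "z_wave2", "delta",
           "decline_direction")
}

#' White matter hyperintensity burden as log percent of brain volume
#'
#' WMH volume is expressed as a percentage of total brain volume (grey +
#' white + CSF) and log-transformed to reduce skewness:
#' percent = 100 * wmh / (grey + white + csf); log_wmh = log_base(percent).
#'
#' @param wmh,grey,white,csf Volumes in a common unit, all positive
#'   (vectorized).
#' @param base Logarithm base (default natural log).
#' @return Tibble: `percent_wmh`, `log_wmh`.
#' @examples
#' wmh_percent_log(14, 530, 480, 390)
#' @export
wmh_percent_log <- function(wmh, grey, white, csf, base = exp(1)) {
  if (any(c(wmh, grey, white, csf) <= 0)) {
    abort("All volumes must be positive.")
  }
  percent <- 100 * wmh / (grey + white + csf)
  tibble(percent_wmh = percent, log_wmh = log(percent, base = base))
}

#' Longitudinal WMH change
#'
#' Absolute difference of log-transformed WMH percentages between waves;
#' positive values represent an increase in WMH burden from wave 1 to 2.
#'
#' @param log_wmh_wave1,log_wmh_wave2 Log WMH percent at each wave (same
#'   base).
#' @return `log_wmh_wave2 - log_wmh_wave1`.
#' @export
wmh_change <- function(log_wmh_wave1, log_wmh_wave2) {
  log_wmh_wave2 - log_wmh_wave1
}
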