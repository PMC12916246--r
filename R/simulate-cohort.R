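#' Default latent distributions for the structural metrics
#'
#' One row per structural metric the cohort generator emulates: bilateral
#' hippocampal and total grey-matter volume (cm^3), and FA/MD/RD/L1
#' (unitless / mm^2/s) for the corpus callosum, cingulum bundle, internal
#' capsule and fornix. `mean`/`sd` set the latent wave-1 distribution,
#' `annual_change` the mean annual drift (negative for volumes and FA,
#' positive for diffusivities, per the ageing literature), `change_sd` the
#' between-participant SD of the annual change, and `noise_sd` the
#' measurement noise added independently at each wave.
#'
#' @return A tibble with columns `metric`, `family`, `tract`, `mean`, `sd`,
#'   `annual_change`, `change_sd`, `noise_sd`.
#' @export
default_metric_table <- function() {
  tracts <- c("corpus_callosum", "cingulum_bundle", "internal_capsule", "fornix")
  gmv <- tibble(
    metric = c("gmv_left_hippocampus", "gmv_right_hippocampus", "gmv_total"),
    family = "gmv", tract = NA_character_,
    mean = c(2.92, 3.07, 531.69),
    sd = c(0.44, 0.40, 45.39)
  )
  dti <- tibble(
    metric = c(paste0("fa_", tracts), paste0("md_", tracts),
               paste0("rd_", tracts), paste0("l1_", tracts)),
    family = rep(c("fa", "md", "rd", "l1"), each = 4),
    tract = rep(tracts, 4),
    mean = c(0.72, 0.60, 0.64, 0.50,
             6.94e-4, 6.56e-4, 6.28e-4, 8.47e-4,
             3.11e-4, 3.85e-4, 3.45e-4, 6.03e-4,
             1.46e-3, 1.20e-3, 1.19e-3, 1.33e-3),
    sd = c(0.03, 0.03, 0.02, 0.04,
           4.18e-5, 2.93e-5, 2.59e-5, 6.62e-5,
           4.51e-5, 3.31e-5, 2.79e-5, 8.38e-5,
           4.81e-5, 4.17e-5, 3.68e-5, 4.99e-5)
  )
  m <- bind_rows(gmv, dti)
  m$annual_change <- dplyr::case_when(
    m$family == "gmv" ~ -0.006 * m$mean,
    m$family == "fa" ~ -0.002,
    TRUE ~ 0.004 * m$mean
  )
  m$change_sd <- 0.05 * m$sd
  m$noise_sd <- 0.1 * m$sd
  m
}

#' Specification of a synthetic two-wave cohort
#'
#' Defines the sampling distributions for a cohort emulating an older-adult
#' two-wave imaging study: ages, inter-wave intervals, sex ratio, hippocampal
#' and whole-brain CVR, latent structural metrics with annual change, white
#' matter hyperintensity (WMH) burden, per-wave scanner affine effects, and
#' planted CVR-structure effects (zero by default, i.e. a null cohort).
#'
#' @param n_participants Number of participants (default 154, the analysed
#'   sample of the emulated study).
#' @param female_fraction Proportion female (default 0.26).
#' @param age_mean,age_sd Age at wave 1, years (default 68.2 / 4.4).
#' @param interval_mean,interval_sd Inter-wave interval, years (default
#'   8.7 / 1.2; truncated below at 1).
#' @param cvr_mean,cvr_sd Latent hippocampal CVR, %/mmHg (default
#'   0.205 / 0.07), drawn from a normal truncated at zero by rejection.
#' @param lr_jitter_sd SD of independent left/right hemisphere jitter around
#'   the latent hippocampal CVR (default 0.02).
#' @param whole_brain_offset,whole_brain_jitter_sd Whole-brain CVR is the
#'   latent hippocampal CVR plus this offset and jitter (defaults 0.075 /
#'   0.03, matching whole-brain grey matter running higher than hippocampus).
#' @param metrics Metric table as in [default_metric_table()].
#' @param cross_sectional_effect Outcome units per (%/mmHg) added to the
#'   latent wave-2 value; scalar (recycled) or named by metric. Default 0.
#' @param longitudinal_effect Annual-change units per (%/mmHg) added to the
#'   latent annual change; scalar or named by metric. Default 0.
#' @param wmh_cs_effect,wmh_long_effect Same, for log WMH percent (default 0).
#' @param scanner_scale Length-2 positive multiplicative scanner effect for
#'   waves 1 and 2 applied to observed volume/diffusion values (default
#'   `c(1, 1.05)`).
#' @param scanner_offset_frac Length-2 additive scanner offset as a fraction
#'   of each metric's mean (default `c(0, 0.02)`).
#' @param wmh_log_mean,wmh_log_sd Natural-log WMH percent at wave 1 (default
#'   1.35 / 0.49).
#' @param wmh_annual_mean,wmh_annual_sd Annual change of log WMH percent
#'   (default 0.023 / 0.015, reaching the observed wave-2 level over a
#'   typical interval).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 154,
                        female_fraction = 0.26,
                        age_mean = 68.2, age_sd = 4.4,
                        interval_mean = 8.7, interval_sd = 1.2,
                        cvr_mean = 0.205, cvr_sd = 0.07,
                        lr_jitter_sd = 0.02,
                        whole_brain_offset = 0.075,
                        whole_brain_jitter_sd = 0.03,
                        metrics = default_metric_table(),
                        cross_sectional_effect = 0,
                        longitudinal_effect = 0,
                        wmh_cs_effect = 0, wmh_long_effect = 0,
                        scanner_scale = c(1, 1.05),
                        scanner_offset_frac = c(0, 0.02),
                        wmh_log_mean = 1.35, wmh_log_sd = 0.49,
                        wmh_annual_mean = 0.023, wmh_annual_sd = 0.015) {
  if (n_participants < 3) abort("`n_participants` must be at least 3.")
  if (any(c(age_sd, interval_sd, cvr_sd, lr_jitter_sd,
            whole_brain_jitter_sd, wmh_log_sd, wmh_annual_sd) < 0)) {
    abort("Standard deviations must be >= 0.")
  }
  if (any(scanner_scale <= 0)) {
    abort("Scanner scale factors must be positive.")
  }
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

resolve_effect <- function(effect, metric_names) {
  if (is.null(names(effect))) {
    if (length(effect) != 1) abort("Unnamed effects must be scalar.")
    return(setNames(rep(effect, length(metric_names)), metric_names))
  }
  out <- setNames(rep(0, length(metric_names)), metric_names)
  bad <- setdiff(names(effect), metric_names)
  if (length(bad)) abort(paste0("Unknown metric in effect: ", toString(bad)))
  out[names(effect)] <- effect
  out
}

#' Simulate a two-wave cohort with known ground truth
#'
#' Draws a cohort under [cohort_spec()]: per participant, age, sex and
#' interval; latent hippocampal CVR (truncated-positive normal) with
#' hemisphere-specific and whole-brain observed values; per metric, a latent
#' wave-1 value, a latent annual change (base rate + planted longitudinal
#' effect x CVR + noise), a latent wave-2 value (wave 1 + change x interval +
#' planted cross-sectional effect x CVR), and observed values per wave
#' (scanner scale x latent + offset + measurement noise). WMH is generated on
#' the natural-log percent scale with its own planted effects and converted
#' to volumes via simulated grey/white/CSF tissue volumes.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed fixing all randomness.
#' @return A `cvr_cohort` list with elements
#'   \describe{
#'     \item{participants}{tibble: `participant`, `sex`, `age_wave1`,
#'       `age_wave2`, `interval_years`, `cvr_left_hippocampus`,
#'       `cvr_right_hippocampus`, `cvr_whole_brain`.}
#'     \item{measurements}{long tibble: `participant`, `wave` (1/2),
#'       `metric`, `value` in native units. Includes the volume/diffusion
#'       metrics plus `wmh_volume`, `gm_volume`, `wm_volume`, `csf_volume`.}
#'     \item{truth}{list with the latent CVR vector, the per-metric planted
#'       effects and the spec.}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_participants = 20), seed = 42)
#' coh$participants
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  m <- spec$metrics
  cs_eff <- resolve_effect(spec$cross_sectional_effect, m$metric)
  lg_eff <- resolve_effect(spec$longitudinal_effect, m$metric)

  withr::with_seed(seed, {
    sex <- ifelse(runif(n) < spec$female_fraction, "female", "male")
    age1 <- rnorm(n, spec$age_mean, spec$age_sd)
    interval <- pmax(rnorm(n, spec$interval_mean, spec$interval_sd), 1)
    cvr <- rtruncnorm_pos(n, spec$cvr_mean, spec$cvr_sd)
    cvr_l <- jitter_pos(cvr, spec$lr_jitter_sd)
    cvr_r <- jitter_pos(cvr, spec$lr_jitter_sd)
    cvr_wb <- jitter_pos(cvr + spec$whole_brain_offset,
                         spec$whole_brain_jitter_sd)

    participants <- tibble(
      participant = sprintf("P%03d", seq_len(n)),
      sex = sex,
      age_wave1 = age1,
      age_wave2 = age1 + interval,
      interval_years = interval,
      cvr_left_hippocampus = cvr_l,
      cvr_right_hippocampus = cvr_r,
      cvr_whole_brain = cvr_wb
    )

    meas <- vector("list", nrow(m))
    for (j in seq_len(nrow(m))) {
      latent1 <- rnorm(n, m$mean[j], m$sd[j])
      annual <- m$annual_change[j] + lg_eff[m$metric[j]] * cvr +
        rnorm(n, 0, m$change_sd[j])
      latent2 <- latent1 + annual * interval + cs_eff[m$metric[j]] * cvr
      obs1 <- spec$scanner_scale[1] * latent1 +
        spec$scanner_offset_frac[1] * m$mean[j] + rnorm(n, 0, m$noise_sd[j])
      obs2 <- spec$scanner_scale[2] * latent2 +
        spec$scanner_offset_frac[2] * m$mean[j] + rnorm(n, 0, m$noise_sd[j])
      meas[[j]] <- tibble(
        participant = rep(participants$participant, 2),
        wave = rep(c(1L, 2L), each = n),
        metric = m$metric[j],
        value = c(obs1, obs2)
      )
    }

    # WMH and tissue volumes (not scanner-affected; lesion segmentation is
    # assumed consistent across scanners)
    gm1 <- rnorm(n, 545, 45); gm2 <- gm1 * (1 - 0.0015 * interval)
    wm1 <- rnorm(n, 480, 45); wm2 <- wm1 * (1 - 0.0010 * interval)
    cs1 <- rnorm(n, 390, 40); cs2 <- cs1 * (1 + 0.0060 * interval)
    logw1 <- rnorm(n, spec$wmh_log_mean, spec$wmh_log_sd)
    wmh_annual <- rnorm(n, spec$wmh_annual_mean, spec$wmh_annual_sd) +
      spec$wmh_long_effect * cvr
    logw2 <- logw1 + wmh_annual * interval + spec$wmh_cs_effect * cvr
    wmhv1 <- (gm1 + wm1 + cs1) * exp(logw1) / 100
    wmhv2 <- (gm2 + wm2 + cs2) * exp(logw2) / 100

    tissue <- tibble(
      participant = rep(participants$participant, 8),
      wave = rep(rep(c(1L, 2L), each = n), 4),
      metric = rep(c("wmh_volume", "gm_volume", "wm_volume", "csf_volume"),
                   each = 2 * n),
      value = c(wmhv1, wmhv2, gm1, gm2, wm1, wm2, cs1, cs2)
    )

    measurements <- bind_rows(bind_rows(meas), tissue)
  })

  truth <- list(
    cvr_latent = cvr,
    effects = tibble(
      metric = m$metric,
      cross_sectional_effect = unname(cs_eff),
      longitudinal_effect = unname(lg_eff)
    ),
    wmh_cs_effect = spec$wmh_cs_effect,
    wmh_long_effect = spec$wmh_long_effect,
    spec = spec
  )
  structure(
    list(participants = participants, measurements = measurements,
         truth = truth),
    class = "cvr_cohort"
  )
}

# add zero-mean jitter, rejection-resampling draws that land at or below 0
jitter_pos <- function(base, sd) {
  if (sd == 0) return(base)
  out <- base + rnorm(length(base), 0, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- base[bad] + rnorm(length(bad), 0, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

# positive-truncated normal by rejection sampling
rtruncnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' @export
print.cvr_cohort <- function(x, ...) {
  cat(sprintf(
    "<cvr_cohort> %d participants, %d measurements (%d metrics x 2 waves)\n",
    nrow(x$participants), nrow(x$measurements),
    length(unique(x$measurements$metric))
  ))
  invisible(x)
}
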