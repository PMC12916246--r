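#' Read a capnometry trace from delimited text
#'
#' Expects two numeric columns, time in seconds and CO2 partial pressure in
#' mmHg (header `time_s, co2_mmHg` or any two columns in that order), with
#' strictly increasing time. The sampling rate is inferred as the reciprocal
#' of the median time step, so mildly irregular sampling is accepted.
#'
#' @param path File path.
#' @return A [capno_trace()].
#' @export
read_capno_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(d) < 2) abort("Expected two columns: time_s, co2_mmHg.")
  d <- d[, 1:2]
  names(d) <- c("time", "co2")
  bad <- which(!vapply(d, is.numeric, logical(1)))
  if (length(bad)) {
    nonnum <- which(is.na(suppressWarnings(as.numeric(d[[bad[1]]]))))[1]
    abort(sprintf("Non-numeric value in column %d, row %s.", bad[1],
                  ifelse(is.na(nonnum), "?", nonnum)))
  }
  if (anyNA(d$time) || anyNA(d$co2)) {
    abort(sprintf("Non-numeric or missing cell at row %s.",
                  which(is.na(d$time) | is.na(d$co2))[1]))
  }
  if (is.unsorted(d$time, strictly = TRUE)) {
    abort("Time column must be strictly increasing.")
  }
  capno_trace(d$time, d$co2)
}

#' Write a capnometry trace as delimited text
#'
#' Two-column CSV (`time_s`, `co2_mmHg`) at full double precision, so a
#' write/read round-trip preserves values exactly.
#'
#' @param trace A [capno_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capno_csv <- function(trace, path) {
  readr::write_csv(
    tibble(time_s = trace$time, co2_mmHg = trace$co2),
    path
  )
  invisible(path)
}

#' Write and read cohort tables
#'
#' A cohort is stored as two CSVs: `<stem>_participants.csv` and
#' `<stem>_measurements.csv`, in the column layout of [simulate_cohort()].
#'
#' @param cohort A `cvr_cohort` (or compatible list).
#' @param stem Path stem (no extension).
#' @return `write_cohort_csv()` returns the two paths invisibly;
#'   `read_cohort_csv()` a `cvr_cohort` (without ground truth).
#' @export
write_cohort_csv <- function(cohort, stem) {
  pp <- paste0(stem, "_participants.csv")
  pm <- paste0(stem, "_measurements.csv")
  readr::write_csv(cohort$participants, pp)
  readr::write_csv(cohort$measurements, pm)
  invisible(c(pp, pm))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(stem) {
  pp <- paste0(stem, "_participants.csv")
  pm <- paste0(stem, "_measurements.csv")
  for (p in c(pp, pm)) if (!file.exists(p)) abort(paste0("File not found: ", p))
  structure(
    list(
      participants = readr::read_csv(pp, show_col_types = FALSE),
      measurements = readr::read_csv(pm, show_col_types = FALSE),
      truth = NULL
    ),
    class = "cvr_cohort"
  )
}

#' Write and read volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving voxel values at double precision.
#' `read_roi_mask()` additionally checks that the mask is binary and, if a
#' reference array is given, that the grids match.
#'
#' @param x 3-D or 4-D numeric array (a `cvr_map`'s `cvr` array works).
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param reference Optional array whose spatial grid the mask must match.
#' @return `write_nifti_volume()` returns `path` invisibly; the readers
#'   return arrays (masks as logical).
#' @export
write_nifti_volume <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr), dim = dim(arr))
}

#' @rdname write_nifti_volume
#' @export
read_roi_mask <- function(path, reference = NULL) {
  arr <- read_nifti_volume(path)
  if (!all(arr %in% c(0, 1))) {
    abort("Mask must be binary (0/1).")
  }
  if (!is.null(reference) &&
      !identical(dim(arr), dim(reference)[seq_along(dim(arr))])) {
    abort("Mask grid does not match the reference grid.")
  }
  array(arr > 0, dim = dim(arr))
}

run_config_defaults <- function() {
  list(
    paradigm = list(gas = c("air", "co2", "air", "co2", "air"),
                    duration = c(60, 75, 75, 75, 75)),
    breathing_rate = 12,
    baseline_etco2 = 40,
    hypercapnic_boost = 8,
    transition_time_constant = 10,
    inspiratory_floor = 2,
    sampling_rate = 20,
    plateau_fraction = 0.3,
    repetition_time = 3,
    n_volumes = 120,
    drift_order = 1,
    delay_mode = "none",
    max_delay = 15,
    delay_step = 0.5,
    slope_tolerance = 0.02,
    baseline_tolerance = 2,
    mad_multiplier = 6,
    wmh_log_base = exp(1),
    sex_reference = "female",
    seed = 1,
    output_dir = "."
  )
}

#' Load a run configuration from YAML
#'
#' Every field has a documented default (see the returned object); unknown
#' keys and type mismatches are rejected by name. An empty file yields all
#' defaults. The MAD outlier multiplier defaults to 6.
#'
#' @param path YAML file path.
#' @return A `run_config` list with the full effective configuration.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key: ", toString(unknown)))
  }
  cfg <- defaults
  for (k in names(user)) {
    if (k == "paradigm") {
      cfg$paradigm <- user$paradigm
      next
    }
    expected <- class(defaults[[k]])[1]
    value <- user[[k]]
    if (expected == "numeric" && is.numeric(value)) value <- as.numeric(value)
    if (!identical(class(value)[1], expected)) {
      abort(sprintf("Key `%s` must be of type %s.", k, expected))
    }
    cfg[[k]] <- value
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in setdiff(names(x), "paradigm")) {
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  cat(sprintf("  paradigm: %s\n",
              paste(x$paradigm$gas, x$paradigm$duration, collapse = " | ")))
  invisible(x)
}
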