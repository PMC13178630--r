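#' Lateral scan geometry of a raster-scanned AO-OCT field
#'
#' Sampling intervals of the fast and slow scan dimensions for a square
#' field of view, and the Nyquist minimum sampling interval for a given
#' lateral resolution (half the resolution, for a continuous signal).
#'
#' @param n_fast A-scans per B-scan.
#' @param n_slow B-scans per volume.
#' @param fov_um Field-of-view width in micrometers (1 degree of visual
#'   angle taken as 300 um).
#' @param lateral_resolution_um Lateral optical resolution in micrometers.
#' @return List with `fast_sampling_um`, `slow_sampling_um`,
#'   `nyquist_interval_um`, and logical `nyquist_satisfied` per dimension.
#' @export
#' @examples
#' scan_geometry()  # 1.875 um fast, ~1.744 um slow, 1.6 um Nyquist
scan_geometry <- function(n_fast = 160, n_slow = 172, fov_um = 300,
                          lateral_resolution_um = 3.2) {
  fast <- fov_um / n_fast
  slow <- fov_um / n_slow
  nyq <- lateral_resolution_um / 2
  list(
    fast_sampling_um = fast,
    slow_sampling_um = slow,
    nyquist_interval_um = nyq,
    nyquist_satisfied = c(fast = fast <= nyq, slow = slow <= nyq)
  )
}

#' Run the full ORG pipeline: simulate, extract, fit, report
#'
#' Executes all stages in order on a simulated cohort, persists the
#' intermediate artifacts (traces and fit tables as CSV, the report as
#' JSON with the full configuration and seed embedded), and returns the
#' results. Per-cone exclusions (motion gaps, masked baselines, fit
#' failures, RMS filtering) are logged in the exclusions table.
#'
#' @param out_dir Output directory (created if missing).
#' @param pop_config An [org_pop_config()].
#' @param acq_config An [org_acq_config()].
#' @param n_trials Number of repeated trials.
#' @param seed Integer seed controlling all randomness.
#' @param rms_threshold RMS fit-error threshold in nm.
#' @param rms_sensitivity Additional thresholds for the retained-fraction
#'   sensitivity summary.
#' @param stimulus_on If `FALSE`, runs the no-stimulus control condition.
#' @param m Number of brightest A-scans (default: acquisition setting).
#' @param write_dataset Also persist the raw simulated dataset
#'   (`dataset.rds`).
#' @return Invisibly, a list with `report` (an
#'   [org_repeatability_report][repeatability_report] when computable),
#'   `fit_table`, `retained`, `retained_fraction`, `exclusions`,
#'   `noise_floor_rms_nm` (RMS of the baseline-window / control trace
#'   values), and `paths`.
#' @export
run_org_pipeline <- function(out_dir,
                             pop_config = org_pop_config(),
                             acq_config = org_acq_config(),
                             n_trials = 3,
                             seed = 1,
                             rms_threshold = 30,
                             rms_sensitivity = c(20, 30, 40),
                             stimulus_on = TRUE,
                             m = NULL,
                             write_dataset = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- simulate_dataset(pop_config, acq_config, n_trials = n_trials,
                              seed = seed, stimulus_on = stimulus_on)
  ex <- extract_traces(dataset, m = m)
  fit_table <- fit_cohort(ex$traces)
  fl <- filter_by_rms(fit_table, rms_threshold)
  sens <- vapply(rms_sensitivity,
                 function(th) filter_by_rms(fit_table, th)$retained_fraction,
                 numeric(1))
  names(sens) <- paste0("rms_", rms_sensitivity, "_nm")

  # noise floor: RMS of the trace about zero where no response is expected
  nf_vals <- if (stimulus_on) {
    ex$traces$dopl_nm[ex$traces$t <= 0 & !ex$traces$masked]
  } else {
    ex$traces$dopl_nm[!ex$traces$masked]
  }
  noise_floor <- if (length(nf_vals)) sqrt(mean(nf_vals^2)) else NA_real_

  report <- NULL
  if (n_trials >= 2 && nrow(fl$retained) > 0) {
    report <- tryCatch(repeatability_report(fl$retained),
                       error = function(e) NULL)
  }

  excl <- rbind(ex$exclusions, attr(fit_table, "exclusions"))
  paths <- list(
    traces = file.path(out_dir, "traces.csv"),
    fits = file.path(out_dir, "fits.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    report = file.path(out_dir, "report.json")
  )
  write.csv(ex$traces, paths$traces, row.names = FALSE)
  write.csv(fit_table, paths$fits, row.names = FALSE)
  write.csv(excl, paths$exclusions, row.names = FALSE)
  if (write_dataset) {
    paths$dataset <- file.path(out_dir, "dataset.rds")
    write_org_dataset(dataset, paths$dataset)
  }

  json <- list(
    seed = seed,
    config = list(
      acquisition = unclass(acq_config),
      population = unclass(pop_config),
      n_trials = n_trials,
      rms_threshold = rms_threshold,
      stimulus_on = stimulus_on
    ),
    retained_fraction = fl$retained_fraction,
    retained_fraction_sensitivity = as.list(sens),
    noise_floor_rms_nm = noise_floor,
    n_exclusions = nrow(excl),
    repeatability = report_to_list(report)
  )
  jsonlite::write_json(json, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    report = report,
    fit_table = fit_table,
    retained = fl$retained,
    retained_fraction = fl$retained_fraction,
    retained_fraction_sensitivity = sens,
    exclusions = excl,
    noise_floor_rms_nm = noise_floor,
    paths = paths
  ))
}

# flatten a repeatability report for JSON serialization
report_to_list <- function(report) {
  if (is.null(report)) return(NULL)
  lapply(unclass(report), function(p) list(
    cov_rms = p$cov_rms,
    cov_mean = p$cov_mean,
    icc = p$icc$icc,
    icc_ci = c(p$icc$ci_lower, p$icc$ci_upper),
    icc_degenerate = p$icc$degenerate,
    trial_means = unname(p$pooled$trial_means),
    trial_sds = unname(p$pooled$trial_sds),
    cov_of_means = p$pooled$cov_of_means,
    cov_of_sds = p$pooled$cov_of_sds,
    n_complete_cones = p$n_complete_cones
  ))
}
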