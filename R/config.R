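#' Acquisition configuration
#'
#' Describes the AO-OCT ORG acquisition geometry and timing. Defaults follow
#' a 28 Hz volume rate with two pre-stimulus (baseline) volumes, 42
#' post-stimulus volumes, a 10 ms stimulus flash delivered at `t = 0` and a
#' 1063 nm center wavelength. Each cone is sampled by a `region_size` x
#' `region_size` block of A-scans, of which the `m_brightest` are used by the
#' phase estimator.
#'
#' Time is referenced to stimulus onset: the baseline volumes sit at negative
#' times and the first post-stimulus sample falls at `1/volume_rate` (plus
#' `time_offset`, which can represent a sub-frame offset between flash and
#' first sample).
#'
#' @param volume_rate Volume rate in Hz.
#' @param n_volumes Number of post-stimulus volumes.
#' @param n_baseline_volumes Number of pre-stimulus volumes used for phase
#'   referencing (at least 2).
#' @param stimulus_duration Stimulus flash duration in seconds.
#' @param wavelength Imaging center wavelength in nm.
#' @param region_size Side of the square A-scan block containing one cone.
#' @param m_brightest Number of brightest A-scans entering the estimator.
#' @param time_offset Optional sub-frame time offset in seconds added to all
#'   sample times.
#' @return An object of class `org_acq_config`.
#' @seealso [org_time_vector()], [org_pop_config()]
#' @export
#' @examples
#' acq <- org_acq_config()
#' range(org_time_vector(acq))
org_acq_config <- function(volume_rate = 28,
                           n_volumes = 42,
                           n_baseline_volumes = 2,
                           stimulus_duration = 0.010,
                           wavelength = 1063,
                           region_size = 7,
                           m_brightest = 9,
                           time_offset = 0) {
  if (volume_rate <= 0) stop("volume_rate must be positive")
  if (n_volumes < 1) stop("n_volumes must be at least 1")
  if (n_baseline_volumes < 2) {
    stop("n_baseline_volumes must be at least 2 (baseline phase referencing)")
  }
  if (wavelength <= 0) stop("wavelength must be positive")
  if (region_size < 1) stop("region_size must be at least 1")
  if (m_brightest < 1 || m_brightest > region_size^2) {
    stop("m_brightest must lie in [1, region_size^2]")
  }
  structure(list(
    volume_rate = volume_rate,
    n_volumes = as.integer(n_volumes),
    n_baseline_volumes = as.integer(n_baseline_volumes),
    stimulus_duration = stimulus_duration,
    wavelength = wavelength,
    region_size = as.integer(region_size),
    m_brightest = as.integer(m_brightest),
    time_offset = time_offset
  ), class = "org_acq_config")
}

#' Sample times of an ORG recording
#'
#' Sample times in seconds relative to stimulus onset: baseline volumes at
#' negative times, first post-stimulus volume at `1/volume_rate`.
#'
#' @param acq_config An [org_acq_config()].
#' @return Numeric vector of length `n_baseline_volumes + n_volumes`.
#' @export
org_time_vector <- function(acq_config) {
  stopifnot(inherits(acq_config, "org_acq_config"))
  k <- c(-rev(seq_len(acq_config$n_baseline_volumes)) + 0,
         seq_len(acq_config$n_volumes))
  k / acq_config$volume_rate + acq_config$time_offset
}

#' Cone population configuration
#'
#' Describes the statistical structure of a cone cohort and of the
#' measurement noise the simulator emulates. Amplitude and rate means and
#' dispersions default to the scale observed for pooled in vivo cone
#' responses at ~3-4 degrees eccentricity (maximum elongation about
#' 190 +/- 46 nm, elongation rate about 8 +/- 2 s^-1, slow-return rate about
#' 1 +/- 0.3 s^-1).
#'
#' @param n_cones Number of cones in the cohort.
#' @param mean_A1,sd_A1 Mean and SD (nm) of the model amplitude `A1`
#'   (normal, truncated at zero).
#' @param mean_tau_a,sd_tau_a Mean and SD (s^-1) of the elongation rate.
#' @param mean_tau_b,sd_tau_b Mean and SD (s^-1) of the slow-return rate;
#'   `tau_a > tau_b > 0` is enforced by resampling.
#' @param s_cone_fraction Fraction of cones emulating the weakly responding
#'   S-cone subpopulation.
#' @param s_cone_amplitude_range Length-2 range (nm) of S-cone-like
#'   amplitudes, drawn uniformly.
#' @param trial_noise_sd Cone-level trial-to-trial response jitter expressed
#'   in nm of amplitude; applied multiplicatively to `A1` and on the log
#'   scale to both rates at relative scale `trial_noise_sd / mean_A1`.
#' @param snr_db OCT amplitude signal-to-noise ratio in dB at the mean
#'   A-scan amplitude; per-A-scan phase noise SD is `1/SNR` (linear),
#'   scaled inversely with each A-scan's amplitude.
#' @param dropout_rate Probability that a timepoint is lost to eye motion.
#' @param baseline_drift_rms RMS (nm) of the slow baseline optical path
#'   length drift (the no-stimulus noise floor is ~2.5 nm RMS).
#' @param amplitude_sdlog Log-scale SD of the per-A-scan (speckle-like)
#'   amplitude distribution.
#' @return An object of class `org_pop_config`.
#' @export
#' @examples
#' pop <- org_pop_config(n_cones = 50)
org_pop_config <- function(n_cones = 300,
                           mean_A1 = 190,
                           sd_A1 = 46,
                           mean_tau_a = 8,
                           sd_tau_a = 2,
                           mean_tau_b = 1,
                           sd_tau_b = 0.3,
                           s_cone_fraction = 0.05,
                           s_cone_amplitude_range = c(30, 50),
                           trial_noise_sd = 10,
                           snr_db = 25,
                           dropout_rate = 0.05,
                           baseline_drift_rms = 2.5,
                           amplitude_sdlog = 0.6) {
  if (n_cones < 1) stop("n_cones must be positive")
  if (any(c(sd_A1, sd_tau_a, sd_tau_b, trial_noise_sd,
            baseline_drift_rms, amplitude_sdlog) < 0)) {
    stop("standard deviations must be non-negative")
  }
  if (mean_A1 <= 0) stop("mean_A1 must be positive")
  if (s_cone_fraction < 0 || s_cone_fraction >= 1) {
    stop("s_cone_fraction must lie in [0, 1)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  if (length(s_cone_amplitude_range) != 2 ||
      diff(s_cone_amplitude_range) < 0) {
    stop("s_cone_amplitude_range must be an increasing length-2 vector")
  }
  structure(list(
    n_cones = as.integer(n_cones),
    mean_A1 = mean_A1, sd_A1 = sd_A1,
    mean_tau_a = mean_tau_a, sd_tau_a = sd_tau_a,
    mean_tau_b = mean_tau_b, sd_tau_b = sd_tau_b,
    s_cone_fraction = s_cone_fraction,
    s_cone_amplitude_range = s_cone_amplitude_range,
    trial_noise_sd = trial_noise_sd,
    snr_db = snr_db,
    dropout_rate = dropout_rate,
    baseline_drift_rms = baseline_drift_rms,
    amplitude_sdlog = amplitude_sdlog
  ), class = "org_pop_config")
}

# phase noise SD (rad) per A-scan at the mean amplitude; shot-noise-limited
# approximation sigma_phi = 1/SNR (amplitude SNR, linear)
phase_noise_sd <- function(snr_db) {
  if (is.infinite(snr_db)) return(0)
  10^(-snr_db / 20)
}
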