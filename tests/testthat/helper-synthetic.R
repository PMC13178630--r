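# shared fixtures, built in code

# a configuration with every noise source switched off
noise_free_pop <- function(n_cones = 3, mean_A1 = 190, mean_tau_a = 8,
                           mean_tau_b = 1) {
  org_pop_config(
    n_cones = n_cones,
    mean_A1 = mean_A1, sd_A1 = 0,
    mean_tau_a = mean_tau_a, sd_tau_a = 0,
    mean_tau_b = mean_tau_b, sd_tau_b = 0,
    s_cone_fraction = 0,
    trial_noise_sd = 0,
    snr_db = Inf,
    dropout_rate = 0,
    baseline_drift_rms = 0
  )
}

# direct model-level trace (bypasses the complex-signal encoding)
make_trace <- function(A1, tau_a, tau_b, noise_sd = 0,
                       acq = org_acq_config(), cone_id = 1L,
                       trial_id = 1L) {
  tt <- org_time_vector(acq)
  y <- rlc_model(tt, A1, tau_a, tau_b) + rnorm(length(tt), 0, noise_sd)
  data.frame(cone_id = cone_id, trial_id = trial_id, t = tt,
             dopl_nm = y, masked = FALSE)
}

# hand-built cone record with explicit phase content
make_record <- function(phase_cost_minus_isos, amplitudes = NULL,
                        n_ascans = 4, piston = NULL,
                        mask = NULL, cone_id = 1L, trial_id = 1L) {
  nt <- length(phase_cost_minus_isos)
  if (is.null(amplitudes)) amplitudes <- rep(1, n_ascans)
  np <- length(amplitudes)
  if (is.null(piston)) piston <- numeric(nt)
  if (is.null(mask)) mask <- rep(FALSE, nt)
  common <- matrix(piston, np, nt, byrow = TRUE)
  isos <- amplitudes * exp(1i * common)
  cost <- amplitudes * exp(1i * (common +
    matrix(phase_cost_minus_isos, np, nt, byrow = TRUE)))
  list(cone_id = cone_id, trial_id = trial_id, class = "LM",
       isos = isos, cost = cost, amplitudes = amplitudes, mask = mask)
}

# phase series wrapper around raw wrapped phases
make_phase_series <- function(phase, mask = NULL, cone_id = 1L,
                              trial_id = 1L) {
  if (is.null(mask)) mask <- rep(FALSE, length(phase))
  phase[mask] <- NA_real_
  structure(list(cone_id = cone_id, trial_id = trial_id,
                 phase = phase, indices = NULL, mask = mask),
            class = "org_phase_series")
}
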