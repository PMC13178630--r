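# wrap angles into (-pi, pi]
wrap_pi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[!is.na(w) & w <= -pi] <- pi
  w
}

# classed condition used to exclude a cone from a trial with a logged reason
org_exclusion <- function(reason, cone_id = NA, trial_id = NA) {
  structure(
    class = c("org_exclusion", "error", "condition"),
    list(message = sprintf("cone %s trial %s excluded: %s",
                           cone_id, trial_id, reason),
         call = NULL, reason = reason,
         cone_id = cone_id, trial_id = trial_id)
  )
}

#' Select the brightest A-scans of a cone region
#'
#' Returns the indices of the `m` largest amplitudes; ties are broken
#' deterministically by the lowest index.
#'
#' @param amplitude_map Numeric vector of A-scan amplitudes (length
#'   `region_size^2`).
#' @param m Number of A-scans to select.
#' @return Integer indices in decreasing order of amplitude.
#' @export
#' @examples
#' select_brightest(c(1, 5, 3, 5), 2)  # 2, 4
select_brightest <- function(amplitude_map, m) {
  if (m < 1 || m > length(amplitude_map)) {
    stop("m must lie in [1, length(amplitude_map)]")
  }
  order(amplitude_map, decreasing = TRUE)[seq_len(m)]
}

#' Conjugate-product phase-difference estimator
#'
#' For each timepoint, the ISOS-COST phase difference is the angle of the
#' mean over the selected A-scans of COST times the complex conjugate of
#' ISOS. Any phase common to both layers (piston, bulk axial motion)
#' cancels in the product. Timepoints where the summed product is zero are
#' masked (undefined angle).
#'
#' @param cone_record A cone record as produced by [simulate_trial()].
#' @param indices Indices of the A-scans entering the estimator (see
#'   [select_brightest()]).
#' @return An object of class `org_phase_series`: list with `cone_id`,
#'   `trial_id`, `phase` (radians in (-pi, pi], `NA` where masked),
#'   `indices`, `mask`.
#' @export
phase_difference <- function(cone_record, indices) {
  if (any(indices < 1 | indices > nrow(cone_record$isos))) {
    stop("invalid A-scan indices")
  }
  prod <- cone_record$cost[indices, , drop = FALSE] *
    Conj(cone_record$isos[indices, , drop = FALSE])
  z <- colMeans(prod)
  phi <- Arg(z)
  mask <- cone_record$mask | Mod(z) == 0 | !is.finite(phi)
  phi[mask] <- NA_real_
  structure(list(
    cone_id = cone_record$cone_id,
    trial_id = cone_record$trial_id,
    phase = phi,
    indices = indices,
    mask = mask
  ), class = "org_phase_series")
}

# per-timepoint brightest-A-scan variant of the estimator
phase_difference_per_timepoint <- function(cone_record, m) {
  nt <- ncol(cone_record$isos)
  phi <- rep(NA_real_, nt)
  mask <- cone_record$mask
  for (t in seq_len(nt)) {
    if (mask[t]) next
    amp <- Mod(cone_record$isos[, t]) * Mod(cone_record$cost[, t])
    idx <- select_brightest(amp, m)
    z <- mean(cone_record$cost[idx, t] * Conj(cone_record$isos[idx, t]))
    if (Mod(z) == 0) {
      mask[t] <- TRUE
    } else {
      phi[t] <- Arg(z)
    }
  }
  structure(list(
    cone_id = cone_record$cone_id,
    trial_id = cone_record$trial_id,
    phase = phi,
    indices = NULL,
    mask = mask
  ), class = "org_phase_series")
}

#' Convert a phase series to an optical path length trace
#'
#' Subtracts the baseline reference phase (circular mean of the unmasked
#' baseline phases, computed on the complex scale to avoid wrap artifacts
#' when baseline phases straddle +/-pi), unwraps the series temporally
#' (adding multiples of 2pi wherever successive unmasked differences exceed
#' pi in magnitude), and scales by `wavelength / (4 pi)` to nm.
#'
#' Cones whose baseline volumes are all masked, or whose masked gaps exceed
#' `max_gap` consecutive samples (unwrap ambiguity), are excluded with a
#' classed condition of class `org_exclusion` carrying the reason.
#'
#' @param phase_series An `org_phase_series` from [phase_difference()].
#' @param acq_config An [org_acq_config()].
#' @param max_gap Longest masked run (in samples) across which phase
#'   continuity is still assumed.
#' @return A data frame with columns `cone_id`, `trial_id`, `t` (s, relative
#'   to stimulus onset), `dopl_nm`, `masked`; attribute `n_baseline_used`
#'   records how many baseline volumes entered the reference.
#' @export
to_opl_trace <- function(phase_series, acq_config, max_gap = 3) {
  stopifnot(inherits(phase_series, "org_phase_series"),
            inherits(acq_config, "org_acq_config"))
  tt <- org_time_vector(acq_config)
  phi <- phase_series$phase
  mask <- phase_series$mask
  if (length(phi) != length(tt)) {
    stop("phase series length does not match the acquisition configuration")
  }
  nb <- acq_config$n_baseline_volumes
  bi <- which(!mask[seq_len(nb)])
  if (length(bi) == 0) {
    stop(org_exclusion("baseline_masked",
                       phase_series$cone_id, phase_series$trial_id))
  }
  ref <- Arg(mean(exp(1i * phi[bi])))
  d <- wrap_pi(phi - ref)
  u <- which(!mask)
  if (length(u) == 0) {
    stop(org_exclusion("all_masked",
                       phase_series$cone_id, phase_series$trial_id))
  }
  if (length(u) >= 2 && any(diff(u) > max_gap + 1)) {
    stop(org_exclusion("motion_gap",
                       phase_series$cone_id, phase_series$trial_id))
  }
  un <- rep(NA_real_, length(tt))
  un[u[1]] <- d[u[1]]
  if (length(u) >= 2) {
    for (k in 2:length(u)) {
      un[u[k]] <- un[u[k - 1]] + wrap_pi(d[u[k]] - d[u[k - 1]])
    }
  }
  out <- data.frame(
    cone_id = phase_series$cone_id,
    trial_id = phase_series$trial_id,
    t = tt,
    dopl_nm = un * acq_config$wavelength / (4 * pi),
    masked = mask
  )
  attr(out, "n_baseline_used") <- length(bi)
  out
}

#' Extract \eqn{\Delta}OPL traces from a simulated dataset
#'
#' Runs [select_brightest()], [phase_difference()] and [to_opl_trace()] for
#' every cone of every trial. By default the brightest A-scans are selected
#' once per trial from the static amplitude map; with
#' `select_per_timepoint = TRUE` they are reselected at each timepoint from
#' the instantaneous amplitudes.
#'
#' @param dataset An `org_dataset` from [simulate_dataset()].
#' @param m Number of brightest A-scans (defaults to the acquisition
#'   configuration's `m_brightest`).
#' @param select_per_timepoint Reselect the brightest A-scans at each
#'   timepoint instead of once per trial.
#' @param max_gap Passed to [to_opl_trace()].
#' @return A list with `traces` (tidy data frame: `cone_id`, `trial_id`,
#'   `t`, `dopl_nm`, `masked`) and `exclusions` (data frame: `cone_id`,
#'   `trial_id`, `reason`).
#' @export
extract_traces <- function(dataset, m = NULL, select_per_timepoint = FALSE,
                           max_gap = 3) {
  stopifnot(inherits(dataset, "org_dataset"))
  acq <- dataset$acq_config
  if (is.null(m)) m <- acq$m_brightest
  traces <- list()
  excl <- list()
  for (trial in dataset$trials) {
    for (rec in trial) {
      ps <- if (select_per_timepoint) {
        phase_difference_per_timepoint(rec, m)
      } else {
        phase_difference(rec, select_brightest(rec$amplitudes, m))
      }
      res <- tryCatch(to_opl_trace(ps, acq, max_gap = max_gap),
                      org_exclusion = function(e) e)
      if (inherits(res, "org_exclusion")) {
        excl[[length(excl) + 1]] <- data.frame(
          cone_id = res$cone_id, trial_id = res$trial_id,
          reason = res$reason, stringsAsFactors = FALSE)
      } else {
        traces[[length(traces) + 1]] <- res
      }
    }
  }
  list(
    traces = if (length(traces)) do.call(rbind, traces) else
      data.frame(cone_id = integer(), trial_id = integer(),
                 t = numeric(), dopl_nm = numeric(), masked = logical()),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(cone_id = integer(), trial_id = integer(),
                 reason = character(), stringsAsFactors = FALSE)
  )
}
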