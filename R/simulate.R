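#' Draw a cone cohort with ground-truth response parameters
#'
#' Draws `n_cones` parameter triplets (`A1`, `tau_a`, `tau_b`) from the
#' configured normal distributions (truncated at zero), enforces
#' `tau_a > tau_b > 0` by resampling, and reassigns a fraction of cones to a
#' weakly responding S-cone-like subpopulation with amplitudes uniform in
#' `s_cone_amplitude_range`.
#'
#' @param pop_config An [org_pop_config()].
#' @param seed Integer seed; the draw is fully deterministic given
#'   (`pop_config`, `seed`).
#' @return A data frame with columns `cone_id`, `class` ("LM" or "S"),
#'   `A1` (nm), `tau_a`, `tau_b` (s^-1).
#' @export
#' @examples
#' gt <- make_cone_population(org_pop_config(n_cones = 20), seed = 1)
#' stopifnot(all(gt$tau_a > gt$tau_b))
make_cone_population <- function(pop_config, seed) {
  stopifnot(inherits(pop_config, "org_pop_config"))
  withr::with_seed(seed, {
    n <- pop_config$n_cones
    A1 <- rnorm_trunc_pos(n, pop_config$mean_A1, pop_config$sd_A1)
    rates <- draw_rate_pairs(n,
                             pop_config$mean_tau_a, pop_config$sd_tau_a,
                             pop_config$mean_tau_b, pop_config$sd_tau_b)
    is_s <- runif(n) < pop_config$s_cone_fraction
    if (any(is_s)) {
      rng <- pop_config$s_cone_amplitude_range
      A1[is_s] <- runif(sum(is_s), rng[1], rng[2])
    }
    data.frame(
      cone_id = seq_len(n),
      class = ifelse(is_s, "S", "LM"),
      A1 = A1,
      tau_a = rates$tau_a,
      tau_b = rates$tau_b,
      stringsAsFactors = FALSE
    )
  })
}

# normal truncated at zero via bounded resampling
rnorm_trunc_pos <- function(n, mean, sd, max_rounds = 1000) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(max_rounds)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("could not draw positive values from N(", mean, ", ", sd, ")")
}

# joint draw with tau_a > tau_b > 0 enforced by resampling
draw_rate_pairs <- function(n, mean_a, sd_a, mean_b, sd_b, max_rounds = 1000) {
  ta <- rnorm(n, mean_a, sd_a)
  tb <- rnorm(n, mean_b, sd_b)
  for (i in seq_len(max_rounds)) {
    bad <- !(ta > tb & tb > 0)
    if (!any(bad)) return(list(tau_a = ta, tau_b = tb))
    ta[bad] <- rnorm(sum(bad), mean_a, sd_a)
    tb[bad] <- rnorm(sum(bad), mean_b, sd_b)
  }
  stop("rate distributions cannot satisfy tau_a > tau_b > 0 ",
       "after bounded resampling")
}

# smooth (random-walk) drift trace scaled to a target RMS, zero mean
make_drift <- function(n, rms) {
  if (rms == 0 || n < 2) return(numeric(n))
  w <- cumsum(rnorm(n))
  w <- w - mean(w)
  s <- sqrt(mean(w^2))
  if (s == 0) return(numeric(n))
  w * rms / s
}

# per-trial realized parameters: multiplicative log-normal jitter on A1 and
# on both rates at relative scale trial_noise_sd / mean_A1
jitter_params <- function(ground_truth, pop_config, max_rounds = 1000) {
  n <- nrow(ground_truth)
  s_rel <- if (pop_config$trial_noise_sd > 0) {
    pop_config$trial_noise_sd / pop_config$mean_A1
  } else 0
  A1 <- ground_truth$A1 * exp(rnorm(n, 0, s_rel))
  ta <- ground_truth$tau_a * exp(rnorm(n, 0, s_rel))
  tb <- ground_truth$tau_b * exp(rnorm(n, 0, s_rel))
  for (i in seq_len(max_rounds)) {
    bad <- !(ta > tb & tb > 0)
    if (!any(bad)) break
    ta[bad] <- ground_truth$tau_a[bad] * exp(rnorm(sum(bad), 0, s_rel))
    tb[bad] <- ground_truth$tau_b[bad] * exp(rnorm(sum(bad), 0, s_rel))
  }
  if (any(!(ta > tb & tb > 0))) {
    stop("trial jitter cannot satisfy tau_a > tau_b > 0")
  }
  data.frame(cone_id = ground_truth$cone_id, class = ground_truth$class,
             A1 = A1, tau_a = ta, tau_b = tb, stringsAsFactors = FALSE)
}

#' Simulate one ORG trial of complex two-layer cone signals
#'
#' For each cone, a clean \eqn{\Delta}OPL(t) curve is computed from the
#' difference-of-exponentials response model (zero before stimulus onset and
#' everywhere when `stimulus_on = FALSE`), perturbed by cone-level trial
#' jitter and a slow baseline drift, and encoded as the ISOS-COST phase
#' difference \eqn{\Delta\phi = 4\pi \Delta OPL / \lambda}. Every timepoint
#' receives an independent common piston phase on both layers (bulk axial
#' motion), each A-scan of each layer receives independent circular Gaussian
#' phase noise with SD set by the amplitude SNR, and a fraction of
#' timepoints is masked (eye-motion dropout).
#'
#' @param ground_truth Cohort data frame from [make_cone_population()].
#' @param acq_config An [org_acq_config()].
#' @param pop_config An [org_pop_config()] (noise and jitter settings).
#' @param seed Integer seed.
#' @param stimulus_on If `FALSE`, simulate the no-stimulus control.
#' @param trial_id Integer trial label stored in each record.
#' @return A list of cone records, each a list with elements `cone_id`,
#'   `trial_id`, `class`, `isos` and `cost` (complex `region_size^2 x
#'   n_timepoints` matrices), `amplitudes`, and `mask` (logical, `TRUE` =
#'   timepoint lost). The per-trial realized parameters are attached as
#'   attribute `"realized"`.
#' @export
simulate_trial <- function(ground_truth, acq_config, pop_config, seed,
                           stimulus_on = TRUE, trial_id = 1L) {
  stopifnot(inherits(acq_config, "org_acq_config"),
            inherits(pop_config, "org_pop_config"))
  sigma0 <- phase_noise_sd(pop_config$snr_db)
  if (sigma0 > pi) {
    stop("snr_db too low: per-A-scan phase noise SD exceeds pi; ",
         "the phase estimator's assumptions are void")
  }
  tt <- org_time_vector(acq_config)
  nt <- length(tt)
  np <- acq_config$region_size^2
  lambda <- acq_config$wavelength
  withr::with_seed(seed, {
    realized <- jitter_params(ground_truth, pop_config)
    piston <- runif(nt, -pi, pi)
    records <- vector("list", nrow(ground_truth))
    for (j in seq_len(nrow(ground_truth))) {
      p <- realized[j, ]
      clean <- if (stimulus_on) {
        rlc_model(tt, p$A1, p$tau_a, p$tau_b)
      } else {
        numeric(nt)
      }
      dopl <- clean + make_drift(nt, pop_config$baseline_drift_rms)
      if (nt > 1 && max(abs(diff(dopl))) >= lambda / 4) {
        stop("configuration rejected: inter-sample OPL step exceeds ",
             "lambda/4, which would break temporal unwrapping")
      }
      dphi <- 4 * pi * dopl / lambda
      a <- rlnorm(np, 0, pop_config$amplitude_sdlog)
      sig <- if (sigma0 == 0) rep(0, np) else sigma0 * mean(a) / a
      phi0 <- runif(np, -pi, pi)       # static per-A-scan phase
      psi0 <- rnorm(np, 0, 0.2)        # static per-A-scan layer offset
      common <- outer(phi0, piston, "+")
      n1 <- matrix(rnorm(np * nt), np, nt) * sig
      n2 <- matrix(rnorm(np * nt), np, nt) * sig
      isos <- a * exp(1i * (common + n1))
      cost <- a * exp(1i * (common + psi0 +
                              matrix(dphi, np, nt, byrow = TRUE) + n2))
      mask <- runif(nt) < pop_config$dropout_rate
      records[[j]] <- list(
        cone_id = ground_truth$cone_id[j],
        trial_id = as.integer(trial_id),
        class = ground_truth$class[j],
        isos = isos, cost = cost,
        amplitudes = a, mask = mask
      )
    }
    attr(records, "realized") <- realized
    records
  })
}

#' Simulate a repeated-trial ORG dataset
#'
#' Draws one ground-truth cohort and simulates `n_trials` independent trials
#' from it (independent noise, jitter, piston, and dropout realizations per
#' trial). Identical (`configs`, `seed`) give identical output.
#'
#' @param pop_config An [org_pop_config()].
#' @param acq_config An [org_acq_config()].
#' @param n_trials Number of repeated trials.
#' @param seed Integer seed for the whole dataset.
#' @param stimulus_on If `FALSE`, all trials are no-stimulus controls.
#' @return An object of class `org_dataset`: a list with elements `trials`
#'   (list of trials, each a list of cone records), `ground_truth`,
#'   `realized` (per-trial realized parameters, long format), `acq_config`,
#'   `pop_config`, `n_trials`, `seed`.
#' @export
#' @examples
#' ds <- simulate_dataset(org_pop_config(n_cones = 5), org_acq_config(),
#'                        n_trials = 2, seed = 1)
#' length(ds$trials)
simulate_dataset <- function(pop_config, acq_config = org_acq_config(),
                             n_trials = 3, seed = 1,
                             stimulus_on = TRUE) {
  stopifnot(n_trials >= 1)
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_trials + 1L))
  ground_truth <- make_cone_population(pop_config, seeds[1])
  trials <- vector("list", n_trials)
  realized <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    trials[[k]] <- simulate_trial(ground_truth, acq_config, pop_config,
                                  seed = seeds[k + 1],
                                  stimulus_on = stimulus_on,
                                  trial_id = k)
    rk <- attr(trials[[k]], "realized")
    rk$trial_id <- k
    realized[[k]] <- rk
  }
  structure(list(
    trials = trials,
    ground_truth = ground_truth,
    realized = do.call(rbind, realized),
    acq_config = acq_config,
    pop_config = pop_config,
    n_trials = as.integer(n_trials),
    seed = seed
  ), class = "org_dataset")
}

#' Persist / load a simulated dataset
#'
#' The dataset container (trials of complex cone records plus ground truth
#' and configuration) is stored as a serialized R object.
#'
#' @param dataset An `org_dataset`.
#' @param path File path.
#' @return `write_org_dataset` returns `path` invisibly; `read_org_dataset`
#'   returns the `org_dataset`.
#' @export
write_org_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "org_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_org_dataset
#' @export
read_org_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "org_dataset")) stop("file does not contain an org_dataset")
  x
}
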