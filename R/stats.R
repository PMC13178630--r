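#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the n-1 sample standard deviation. For
#' nonnegative parameters a non-positive mean makes the CoV meaningless;
#' such inputs return `NA` with a warning so callers can exclude them.
#'
#' @param x Numeric vector, length >= 2.
#' @return CoV in percent, or `NA` if `mean(x) <= 0`.
#' @export
#' @examples
#' cov_pct(c(1, 2, 3))  # 50
cov_pct <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    warning("non-positive mean; CoV undefined, returning NA")
    return(NA_real_)
  }
  100 * sd(x) / m
}

#' Aggregate per-cone CoV values
#'
#' Combines per-cone coefficients of variation across a cohort either as
#' the root-mean-square (the default, consistent with CoV being a standard
#' deviation ratio) or as the arithmetic mean. `NA` values (flagged cones)
#' are dropped.
#'
#' @param per_cone_covs Numeric vector of per-cone CoV values (percent).
#' @param method `"rms"` or `"mean"`.
#' @return Aggregated CoV in percent.
#' @export
#' @examples
#' aggregate_cov(c(3, 4), "rms")   # sqrt(12.5)
#' aggregate_cov(c(3, 4), "mean")  # 3.5
aggregate_cov <- function(per_cone_covs, method = c("rms", "mean")) {
  method <- match.arg(method)
  v <- per_cone_covs[is.finite(per_cone_covs)]
  if (length(v) == 0) stop("no usable CoV values")
  if (method == "rms") sqrt(mean(v^2)) else mean(v)
}

#' Single-measure intraclass correlation ICC(2,1)
#'
#' Two-way ANOVA decomposition with cones as rows and trials as columns:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the row, column and
#' residual mean squares. The 95% confidence interval uses the
#' F-distribution method of McGraw & Wong (1996) for the two-way
#' single-measure absolute-agreement ICC. Negative estimates are reported
#' as computed. A degenerate decomposition (zero residual mean square)
#' yields ICC = 1 with `degenerate = TRUE`.
#'
#' @param param_matrix Numeric matrix, cones x trials; rows with missing
#'   values are dropped (complete-case analysis).
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci_lower`, `ci_upper`, `n`, `k`, mean squares
#'   (`msr`, `msc`, `mse`) and `degenerate`.
#' @export
icc_2_1 <- function(param_matrix, conf_level = 0.95) {
  m <- as.matrix(param_matrix)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) stop("need at least 2 trials")
  if (n < 5) stop("need at least 5 complete cones for a stable ICC")
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  g <- mean(m)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + g)^2) / ((n - 1) * (k - 1))
  scale <- max(msr, msc, mean(m^2), 1e-300)
  if (mse <= 1e-14 * scale) {
    return(list(icc = 1, ci_lower = 1, ci_upper = 1, n = n, k = k,
                msr = msr, msc = msc, mse = mse, degenerate = TRUE))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (1 - icc < 1e-12) {
    ci <- c(icc, icc)
    degenerate <- TRUE
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    )
    degenerate <- FALSE
  }
  list(icc = icc, ci_lower = ci[1], ci_upper = ci[2], n = n, k = k,
       msr = msr, msc = msc, mse = mse, degenerate = degenerate)
}

#' Pooled per-trial statistics
#'
#' For each trial, the parameter values of all retained cones are averaged
#' (pooled response) and their dispersion summarized by the standard
#' deviation. Repeatability of the pooled response is then the CoV across
#' the per-trial means, and stability of the inter-cone dispersion is the
#' CoV across the per-trial standard deviations. Trials may retain
#' different cone subsets.
#'
#' @param per_trial_values List of numeric vectors, one per trial (each the
#'   retained cones' parameter values for that trial).
#' @return List with `trial_means`, `trial_sds`, `cov_of_means`,
#'   `cov_of_sds` (percent).
#' @export
#' @examples
#' pooled_stats(list(rnorm(50, 190, 46), rnorm(60, 190, 46)))
pooled_stats <- function(per_trial_values) {
  if (length(per_trial_values) < 2) stop("need at least 2 trials")
  sizes <- vapply(per_trial_values, length, integer(1))
  if (any(sizes < 2)) stop("every trial needs at least 2 retained cones")
  means <- vapply(per_trial_values, mean, numeric(1))
  sds <- vapply(per_trial_values, sd, numeric(1))
  list(
    trial_means = means,
    trial_sds = sds,
    cov_of_means = cov_pct(means),
    cov_of_sds = if (all(sds > 0) || mean(sds) > 0) cov_pct(sds) else
      NA_real_
  )
}

#' Single-cone and pooled test-retest repeatability report
#'
#' For each parameter of the fit table, computes: per-cone CoV across
#' trials on the complete-case cohort (cones retained in every trial),
#' its RMS and mean aggregates, ICC(2,1) with confidence interval, and
#' pooled per-trial statistics over all retained cones (not just the
#' intersection).
#'
#' @param fit_table Data frame with `cone_id`, `trial_id` and the parameter
#'   columns (typically the retained set from [filter_by_rms()]).
#' @param parameters Named character vector mapping report names to
#'   `fit_table` columns.
#' @param conf_level Confidence level for the ICC interval.
#' @return An object of class `org_repeatability_report`: per parameter a
#'   list with `per_cone_cov`, `cov_rms`, `cov_mean`, `icc` (the
#'   [icc_2_1()] result), `pooled` (the [pooled_stats()] result),
#'   `n_complete_cones`, `n_flagged_cones`.
#' @export
repeatability_report <- function(fit_table,
                                 parameters = c(
                                   dopl_max = "dopl_max_nm",
                                   dopl_fit_max = "dopl_fit_max_nm",
                                   tau_a = "tau_a"),
                                 conf_level = 0.95) {
  trials <- sort(unique(fit_table$trial_id))
  if (length(trials) < 2) stop("repeatability needs at least 2 trials")
  out <- list()
  for (pname in names(parameters)) {
    col <- parameters[[pname]]
    if (!col %in% names(fit_table)) stop("missing column: ", col)
    m <- tapply(fit_table[[col]],
                list(factor(fit_table$cone_id),
                     factor(fit_table$trial_id, levels = trials)),
                mean)
    complete <- m[complete.cases(m), , drop = FALSE]
    covs <- suppressWarnings(apply(complete, 1, cov_pct))
    icc <- icc_2_1(complete, conf_level = conf_level)
    pooled <- pooled_stats(split(fit_table[[col]], fit_table$trial_id))
    out[[pname]] <- list(
      per_cone_cov = covs,
      cov_rms = aggregate_cov(covs, "rms"),
      cov_mean = aggregate_cov(covs, "mean"),
      icc = icc,
      pooled = pooled,
      n_complete_cones = nrow(complete),
      n_flagged_cones = sum(!is.finite(covs))
    )
  }
  structure(out, class = "org_repeatability_report",
            trials = trials)
}

#' @export
print.org_repeatability_report <- function(x, ...) {
  cat("ORG test-retest repeatability report\n")
  for (pname in names(x)) {
    p <- x[[pname]]
    cat(sprintf(
      paste0("  %-14s CoV(rms) %5.2f%%  CoV(mean) %5.2f%%  ",
             "ICC %5.3f [%5.3f, %5.3f]  pooled CoV(means) %5.2f%%  ",
             "CoV(SDs) %5.2f%%  (n=%d cones)\n"),
      pname, p$cov_rms, p$cov_mean,
      p$icc$icc, p$icc$ci_lower, p$icc$ci_upper,
      p$pooled$cov_of_means, p$pooled$cov_of_sds,
      p$n_complete_cones))
  }
  invisible(x)
}
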