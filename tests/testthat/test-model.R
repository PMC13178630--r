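test_that("model curve has the closed-form values", {
  expect_equal(rlc_model(0, 100, 2, 1), 0)
  expect_equal(rlc_model(1e6, 100, 2, 1), 0)
  expect_equal(rlc_model(log(2), 100, 2, 1), 100 * (1 / 2 - 1 / 4))
  expect_error(rlc_model(1, 100, 1, 2), "tau_a > tau_b")
  expect_error(rlc_model(1, 100, 2, 0), "tau_a > tau_b")
})

test_that("analytic peak matches numerical maximization", {
  pk <- rlc_peak(100, 2, 1)
  expect_equal(pk$t_peak, log(2), tolerance = 1e-12)
  expect_equal(pk$peak, 25, tolerance = 1e-12)
  pk2 <- rlc_peak(100, 8, 1)
  expect_equal(pk2$t_peak, log(8) / 7, tolerance = 1e-12)
  withr::with_seed(12, {
    for (i in 1:20) {
      A1 <- runif(1, 30, 300)
      tb <- runif(1, 0.2, 3)
      ta <- tb + runif(1, 0.5, 15)
      pk <- rlc_peak(A1, ta, tb)
      num <- optimize(function(t) rlc_model(t, A1, ta, tb),
                      c(1e-6, 5), maximum = TRUE, tol = 1e-12)
      expect_equal(pk$peak, num$objective, tolerance = 1e-9)
      # stationarity of the closed-form peak time
      h <- 1e-6
      deriv <- (rlc_model(pk$t_peak + h, A1, ta, tb) -
                  rlc_model(pk$t_peak - h, A1, ta, tb)) / (2 * h)
      expect_lt(abs(deriv) / pk$peak, 1e-4)
    }
  })
  expect_error(rlc_peak(100, 2, 2), "tau_a > tau_b")
})

test_that("noise-free traces are recovered to high relative accuracy", {
  withr::with_seed(3, {
    for (i in 1:10) {
      A1 <- runif(1, 40, 300)
      tb <- runif(1, 0.3, 2)
      ta <- tb + runif(1, 2, 12)
      tr <- make_trace(A1, ta, tb)
      f <- fit_rlc(tr)
      expect_true(f$converged)
      expect_lt(abs(f$A1 - A1) / A1, 1e-4)
      expect_lt(abs(f$tau_a - ta) / ta, 1e-4)
      expect_lt(abs(f$tau_b - tb) / tb, 1e-4)
      expect_lt(f$rms_error, 1e-6)
      # returned orientation is always the canonical one
      expect_true(f$A1 > 0 && f$tau_a > f$tau_b)
    }
  })
})

test_that("degenerate traces are flagged, short traces rejected", {
  tt <- org_time_vector(org_acq_config())
  zero <- data.frame(cone_id = 1, trial_id = 1, t = tt,
                     dopl_nm = 0, masked = FALSE)
  f <- fit_rlc(zero)
  expect_false(f$converged)  # amplitude pinned at its lower bound
  expect_lt(f$rms_error, 1e-6)
  short <- data.frame(cone_id = 1, trial_id = 1, t = (1:5) / 28,
                      dopl_nm = 1:5, masked = FALSE)
  expect_error(fit_rlc(short), class = "org_exclusion")
})

test_that("RMS fitting error follows its definition", {
  fit <- structure(list(A1 = 100, tau_a = 2, tau_b = 1), class = "rlc_fit")
  tt <- c(0.1, 0.2)
  base <- data.frame(t = tt, dopl_nm = rlc_model(tt, 100, 2, 1),
                     masked = FALSE)
  expect_equal(rms_fit_error(base, fit), 0)
  plus10 <- base; plus10$dopl_nm <- plus10$dopl_nm + 10
  expect_equal(rms_fit_error(plus10, fit), 10)
  mixed <- base; mixed$dopl_nm <- mixed$dopl_nm + c(-3, 4)
  expect_equal(rms_fit_error(mixed, fit), sqrt(25 / 2))
})

test_that("the RMS filter retains below-threshold converged fits", {
  ft <- data.frame(cone_id = 1:3, trial_id = 1, rms_nm = c(10, 25, 35),
                   converged = TRUE)
  expect_equal(nrow(filter_by_rms(ft, 30)$retained), 2)
  expect_equal(filter_by_rms(ft, 30)$retained_fraction, 2 / 3)
  expect_equal(nrow(filter_by_rms(ft, 40)$retained), 3)
  ft$converged[1] <- FALSE
  expect_equal(nrow(filter_by_rms(ft, 30)$retained), 1)
})

test_that("ORG parameters derive from the five highest samples and the fit", {
  tt <- c(-2 / 28, -1 / 28, (1:7) / 28)
  tr <- data.frame(cone_id = 1, trial_id = 1, t = tt,
                   dopl_nm = c(5, 5, 0, 10, 20, 30, 40, 50, 60),
                   masked = FALSE)
  fit <- structure(list(A1 = 100, tau_a = 2, tau_b = 1), class = "rlc_fit")
  p <- extract_params(tr, fit)
  expect_equal(p$dopl_max, (60 + 50 + 40 + 30 + 20) / 5)  # baselines excluded
  expect_equal(p$dopl_fit_max, 25)
  expect_equal(p$tau_a, 2)
  short <- tr[1:6, ]
  expect_error(extract_params(short, fit), class = "org_exclusion")
})

test_that("direct maxima exceed fitted maxima under zero-mean noise", {
  # selection bias of the five-highest rule near a flat peak
  acq <- org_acq_config()
  withr::with_seed(23, {
    peaks <- replicate(1000, {
      tr <- make_trace(200, 8, 1, noise_sd = 15, acq = acq)
      s <- tr[tr$t > 0, ]
      mean(sort(s$dopl_nm, decreasing = TRUE)[1:5])
    })
    true_peak <- rlc_peak(200, 8, 1)$peak
    expect_gt(mean(peaks), true_peak)
  })
  # without noise the two maxima agree up to temporal sampling error
  tr0 <- make_trace(200, 8, 1)
  f0 <- fit_rlc(tr0)
  p0 <- extract_params(tr0, f0)
  expect_lt(abs(p0$dopl_max - p0$dopl_fit_max), 2)
})

test_that("scaling a trace scales amplitudes and preserves rates", {
  tr <- make_trace(150, 7, 0.8)
  f1 <- fit_rlc(tr)
  tr2 <- tr; tr2$dopl_nm <- 3 * tr2$dopl_nm
  f2 <- fit_rlc(tr2)
  expect_equal(f2$A1, 3 * f1$A1, tolerance = 1e-6)
  expect_equal(f2$tau_a, f1$tau_a, tolerance = 1e-6)
  expect_equal(f2$tau_b, f1$tau_b, tolerance = 1e-6)
  p1 <- extract_params(tr, f1); p2 <- extract_params(tr2, f2)
  expect_equal(p2$dopl_max, 3 * p1$dopl_max, tolerance = 1e-9)
  expect_equal(p2$dopl_fit_max, 3 * p1$dopl_fit_max, tolerance = 1e-6)
})

test_that("rates are consistent across time units", {
  tr <- make_trace(200, 8, 1)
  f_s <- fit_rlc(tr)
  tr_ms <- tr; tr_ms$t <- tr_ms$t * 1000
  f_ms <- fit_rlc(tr_ms,
                  lower = c(1, 0.5e-3, 0.01e-3),
                  upper = c(1000, 0.1, 0.1),
                  starts = list(c(8e-3, 1e-3), c(4e-3, 0.5e-3),
                                c(16e-3, 2e-3)))
  expect_equal(f_ms$tau_a * 1000, f_s$tau_a, tolerance = 1e-4)
  expect_equal(f_ms$tau_b * 1000, f_s$tau_b, tolerance = 1e-4)
  expect_equal(f_ms$A1, f_s$A1, tolerance = 1e-4)
})

test_that("truncation leaves noise-free rate estimates unchanged", {
  tr <- make_trace(190, 8, 1)
  sens <- truncation_sensitivity(tr, durations = c(1.0, 1.1, 1.2),
                                 full = 1.4)
  expect_true(all(sens < 1e-6))
  ident <- truncation_sensitivity(tr, durations = 1.4, full = 1.4)
  expect_equal(unname(ident), 0)
})

test_that("parameter recovery at the noise floor is unbiased", {
  # bias of the estimates over replicates at 15 nm trace noise
  acq <- org_acq_config()
  withr::with_seed(41, {
    fits <- t(replicate(200, {
      tr <- make_trace(200, 8, 1, noise_sd = 15, acq = acq)
      f <- fit_rlc(tr)
      c(f$A1, f$tau_a)
    }))
  })
  expect_lt(abs(mean(fits[, 1]) - 200) / 200, 0.02)
  expect_lt(abs(median(fits[, 2]) - 8) / 8, 0.05)
})
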