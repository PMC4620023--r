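test_that("the Bateman curve vanishes at zero and matches grid maxima", {
  fit <- gcm_fit()
  expect_equal(bateman_conc(fit, 0), 0)
  g <- oracle_grid_argmax(fit)
  expect_equal(g$tmax, 2.944, tolerance = 1e-3)
  expect_equal(fit$tmax, g$tmax, tolerance = 1e-3)
  sol <- soln_fit()
  expect_equal(oracle_grid_argmax(sol)$tmax, 1.816, tolerance = 1e-3)
})

test_that("closed-form peak matches brute force across rate ratios", {
  withr::with_seed(7, {
    for (i in 1:10) {
      ke <- runif(1, 0.05, 1)
      ka <- ke * runif(1, 1.01, 100)
      fit <- bateman_fit(A = runif(1, 1, 100), ka = ka, ke = ke)
      g <- oracle_grid_argmax(fit, t_max = fit$tmax * 3 + 1)
      expect_lte(abs(fit$tmax - g$tmax), 1e-3)
      # the grid value sits below the true peak by O(step^2) curvature
      expect_equal(fit$cmax, g$cmax, tolerance = 1e-4)
    }
  })
})

test_that("peak formulas behave under scaling and in closed form", {
  tc <- tmax_cmax(ka = 2, ke = 1, A = 1)
  expect_equal(tc$tmax, log(2))
  tc10 <- tmax_cmax(ka = 2, ke = 1, A = 10)
  expect_equal(tc10$cmax, 10 * tc$cmax)
  expect_equal(tc10$tmax, tc$tmax)
})

test_that("half-life and elimination rate are exactly reciprocal", {
  fit <- gcm_fit()
  expect_equal(fit$t_half * fit$ke, log(2))
})

test_that("summary calibration reproduces the printed peak exactly", {
  s <- gcm_summary()
  fit <- gcm_fit()
  expect_equal(fit$A, 88.74, tolerance = 1e-3)
  expect_equal(bateman_conc(fit, fit$tmax), s$cmax, tolerance = 1e-12)
  sol <- soln_fit()
  expect_equal(sol$A, 29.44, tolerance = 1e-3)
  expect_equal(bateman_conc(sol, sol$tmax), soln_summary()$cmax,
               tolerance = 1e-12)
  # degenerate but defined: a zero peak calibrates to a zero amplitude
  expect_equal(calibrate_from_summary(1, 0.2, 0)$A, 0)
  expect_error(calibrate_from_summary(-1, 0.2, 10), "> 0")
})

test_that("calibration then peak extraction is the identity on Cmax", {
  withr::with_seed(21, {
    for (i in 1:8) {
      ke <- runif(1, 0.05, 0.5)
      ka <- ke * runif(1, 1.1, 20)
      cmax <- runif(1, 1, 80)
      fit <- calibrate_from_summary(ka, ke, cmax)
      expect_equal(fit$cmax, cmax, tolerance = 1e-12)
    }
  })
})

test_that("degenerate equal-rate curve uses the continuous limiting form", {
  ke <- 0.3
  lim <- bateman_fit(A = 50, ka = ke, ke = ke)
  near <- bateman_fit(A = 50 * ke / 1e-7, ka = ke + 1e-7, ke = ke)
  tt <- c(0.5, 1, 3, 10)
  # A * ke * t * exp(-ke t) is the ka -> ke limit of A' (e^-ke t - e^-ka t)
  # with A' = A * ke / (ka - ke)
  expect_equal(bateman_conc(lim, tt), bateman_conc(near, tt),
               tolerance = 1e-5)
  expect_equal(lim$tmax, 1 / ke)
})

test_that("terminal log-linear slope recovers the elimination rate", {
  tt <- c(6, 12, 24)
  prof <- conc_profile(tt, 10 * exp(-0.1233 * tt))
  tf <- fit_terminal_ke(prof)
  expect_equal(tf$ke, 0.1233, tolerance = 1e-12)
  expect_equal(tf$r_squared, 1)
  expect_true(is.na(tf$flag))
})

test_that("a rising tail is flagged, not silently negated", {
  prof <- conc_profile(c(1, 2, 4, 8), c(1, 2, 4, 8))
  tf <- fit_terminal_ke(prof)
  expect_identical(tf$flag, "non-terminal phase")
  expect_lte(tf$ke, 0)
})

test_that("absorption residue biases the two-point tail slope by < 2%", {
  fit <- gcm_fit()
  tt <- c(12, 24)
  prof <- conc_profile(tt, bateman_conc(fit, tt))
  tf <- fit_terminal_ke(prof, n_terminal = 2)
  expect_equal(tf$ke, 0.1233, tolerance = 0.02)
  expect_false(isTRUE(all.equal(tf$ke, 0.1233)))  # the bias is real
})

test_that("terminal fit rejects unusable inputs", {
  prof <- conc_profile(c(1, 2, 3), c(5, 0, 0))
  expect_error(fit_terminal_ke(prof), "positive")
  ok <- conc_profile(c(1, 2, 3), c(5, 4, 3))
  expect_error(fit_terminal_ke(ok, n_terminal = 1), ">= 2")
})

test_that("noiseless profiles are refit to the generating parameters", {
  fit <- gcm_fit()
  prof <- conc_profile(ocular_sampling_times(),
                       bateman_conc(fit, ocular_sampling_times()))
  re <- fit_bateman(prof)
  expect_equal(re$A, fit$A, tolerance = 1e-3)
  expect_equal(re$ka, fit$ka, tolerance = 1e-3)
  expect_equal(re$ke, fit$ke, tolerance = 1e-3)
})

test_that("unfittable concentration profiles raise errors", {
  expect_error(fit_bateman(conc_profile(1:4, c(0, 0, 0, 0))), "all-zero")
  expect_error(fit_bateman(conc_profile(1:4, c(0, 5, 0, 0))), "positive")
  expect_error(fit_bateman(conc_profile(1:3, c(1, 2, 1))), "at least 4")
})

test_that("analytic AUC matches refining numerical integration", {
  fit <- gcm_fit()
  exact <- bateman_auc(fit)
  expect_equal(exact, fit$A * (1 / fit$ke - 1 / fit$ka))
  for (step in c(0.1, 0.01)) {
    tt <- seq(0, 200, by = step)
    cc <- bateman_conc(fit, tt)
    num <- sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2)
    expect_equal(num, exact, tolerance = if (step == 0.1) 1e-3 else 1e-5)
  }
  # windowed version agrees too
  expect_equal(bateman_auc(fit, 0, 24) + bateman_auc(fit, 24, Inf), exact)
})
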