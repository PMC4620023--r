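test_that("MIC ratios are plain normalization", {
  r <- mic_ratios(51.23, 607.187, 1.22)
  expect_equal(r$cmax_over_mic, 41.99, tolerance = 1e-3)
  expect_equal(r$auc24_over_mic, 497.694, tolerance = 1e-4)
  expect_equal(mic_ratios(1.22, 10, 1.22)$cmax_over_mic, 1)
  expect_equal(mic_ratios(18.98, 121.634, 1.22)$auc24_over_mic, 99.70,
               tolerance = 1e-4)
  expect_error(mic_ratios(1, 1, 0), "> 0")
})

test_that("time above threshold handles the edge regimes", {
  fit <- gcm_fit()
  over <- time_above_threshold(fit, fit$cmax + 1, c(0, 24))
  expect_equal(as.numeric(over), 0)
  expect_false(attr(over, "reached"))
  # vanishing threshold spans the whole window
  expect_equal(as.numeric(time_above_threshold(fit, 1e-9, c(0, 10))), 10,
               tolerance = 1e-3)
  expect_error(time_above_threshold(fit, 0), "> 0")
})

test_that("bisection crossings agree with a fine grid scan", {
  fit <- gcm_fit()
  for (thr in c(1.22, 2.44, 10, 40)) {
    t_above <- as.numeric(time_above_threshold(fit, thr, c(0, Inf)))
    grid <- oracle_grid_time_above(fit, thr, c(0, 60), step = 1e-4)
    expect_lte(abs(t_above - grid), 2e-4, label = sprintf("thr %.3g", thr))
  }
})

test_that("time above threshold is monotone non-increasing in threshold", {
  fit <- soln_fit()
  thr <- seq(0.5, 18, length.out = 15)
  tt <- vapply(thr, function(x) {
    as.numeric(time_above_threshold(fit, x, c(0, Inf)))
  }, numeric(1))
  expect_true(all(diff(tt) <= 1e-9))
})

test_that("area above threshold matches rectangles and limits", {
  fit <- gcm_fit()
  expect_equal(auc_above_threshold(fit, 0, c(0, 24)),
               bateman_auc(fit, 0, 24), tolerance = 1e-5)
  expect_equal(auc_above_threshold(fit, fit$cmax + 1, c(0, 24)), 0)
  # constant toy curve: (10 - 4) * 10 = 60
  flat <- function(t) rep(10, length(t))
  expect_equal(auc_above_threshold(flat, 4, c(0, 10)), 60, tolerance = 1e-6)
  expect_equal(as.numeric(time_above_threshold(flat, 4, c(0, 10))), 10)
})

test_that("the exposure decomposition above a threshold closes", {
  # auc_above + thr * t_above = integral of C over {C > thr}
  withr::with_seed(33, {
    for (i in 1:6) {
      ke <- runif(1, 0.05, 0.4)
      fit <- bateman_fit(A = runif(1, 10, 100), ka = ke * runif(1, 2, 15),
                         ke = ke)
      thr <- runif(1, 0.05, 0.8) * fit$cmax
      w <- c(0, 48)
      above <- auc_above_threshold(fit, thr, w)
      t_ab <- as.numeric(time_above_threshold(fit, thr, w))
      cr <- ocupkpd:::.bateman_crossings(fit, thr, w)
      region_auc <- bateman_auc(fit, max(cr[1], w[1]), min(cr[2], w[2]))
      expect_equal(above + thr * t_ab, region_auc, tolerance = 1e-4)
      expect_lte(above, bateman_auc(fit, w[1], w[2]) + 1e-9)
    }
  })
})

test_that("area above threshold is non-increasing and convex in threshold", {
  fit <- gcm_fit()
  thr <- seq(0.5, 50, length.out = 20)
  a <- vapply(thr, function(x) auc_above_threshold(fit, x, c(0, 48)),
              numeric(1))
  expect_true(all(diff(a) <= 1e-9))
  expect_true(all(diff(diff(a)) >= -1e-4))
})

test_that("dosing interval is the post-peak threshold down-crossing", {
  gcm <- gcm_fit()
  tau <- dosing_interval(gcm, mic90 = 1.22, k = 2)
  expect_equal(tau, oracle_grid_down_crossing(gcm, 2.44), tolerance = 1e-3)
  expect_equal(tau, 28.1, tolerance = 0.05)
  sol <- soln_fit()
  tau_s <- dosing_interval(sol, mic90 = 1.22, k = 2)
  expect_equal(tau_s, oracle_grid_down_crossing(sol, 2.44), tolerance = 1e-3)
  # threshold approaching the peak pushes the interval to Tmax
  eps_tau <- dosing_interval(gcm, mic90 = (gcm$cmax - 1e-6) / 2, k = 2)
  expect_equal(eps_tau, gcm$tmax, tolerance = 1e-2)
  expect_error(dosing_interval(gcm, mic90 = 30, k = 2), "never reached")
})

test_that("the per-arm report carries provenance and consistent values", {
  s <- gcm_summary()
  rep <- pkpd_report(gcm_fit(), mic90 = 1.22, k = 2,
                     cmax = s$cmax, auc_0_24 = s$auc_0_24)
  expect_equal(rep$cmax_over_mic, s$cmax / 1.22)
  expect_equal(rep$auc24_over_mic, s$auc_0_24 / 1.22)
  expect_identical(unname(rep$provenance["cmax"]), "summary")
  expect_true(rep$flags$cmax_mic_over_10)
  expect_true(rep$flags$auc_mic_over_125)
  expect_gte(rep$t_above_mic, rep$t_above_k_mic)
  expect_equal(rep$dosing_interval_tau,
               dosing_interval(gcm_fit(), 1.22, 2))
  # model-provenance fallback uses the curve's own exposure
  m <- pkpd_report(gcm_fit(), mic90 = 1.22)
  expect_identical(unname(m$provenance["cmax"]), "model")
  expect_equal(m$auc_0_24, bateman_auc(gcm_fit(), 0, 24))
})
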