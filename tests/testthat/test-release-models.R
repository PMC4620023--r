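test_that("model evaluation matches the closed forms", {
  expect_equal(eval_release_model("higuchi", c(kH = 20), 4), 40)
  # zero-rate cube-root law leaves everything unreleased
  expect_equal(
    eval_release_model("hixson_crowell", c(kHC = 0, q0 = 100), c(1, 5, 24)),
    c(0, 0, 0))
  expect_equal(
    eval_release_model("hixson_crowell", c(kHC = 0, q0 = 100), 3,
                       form = "remaining"), 100)
  # single-exponential spherical-matrix form, hand arithmetic:
  # 100 * (1 - (6/pi^2) * exp(-1)) = 77.6356
  expect_equal(eval_release_model("baker_lonsdale", c(kBL = 0.5), 2),
               77.6356, tolerance = 1e-5)
  expect_equal(eval_release_model("first_order", c(k1 = 0.2), 0), 0)
  expect_equal(eval_release_model("korsmeyer_peppas", c(k = 45, n = 0.3), 0),
               0)
})

test_that("evaluation rejects bad model names and constants", {
  expect_error(eval_release_model("zeroth_order", c(k = 1), 1),
               "unknown release model")
  expect_error(eval_release_model("higuchi", c(k1 = 1), 1), "missing")
  expect_error(eval_release_model("higuchi", c(kH = -2), 1), "negative")
  expect_error(eval_release_model("korsmeyer_peppas", c(k = 1, n = 0), 1),
               "n must be > 0")
  expect_error(eval_release_model("higuchi", c(kH = 1), -1), ">= 0")
})

test_that("released-form curves are monotone non-decreasing in time", {
  tt <- seq(0, 24, by = 0.25)
  cases <- list(
    list("first_order", c(k1 = 0.3)),
    list("higuchi", c(kH = 15)),
    list("baker_lonsdale", c(kBL = 0.2)),
    list("hixson_crowell", c(kHC = 0.8)),
    list("baker_lonsdale_classical", c(k = 0.03))
  )
  for (cs in cases) {
    q <- eval_release_model(cs[[1]], cs[[2]], tt)
    expect_true(all(diff(q) >= -1e-12), info = cs[[1]])
  }
})

test_that("noiseless data generated by each model are recovered exactly", {
  tt <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 12)
  truth <- list(
    first_order = c(k1 = 0.25),
    higuchi = c(kH = 20),
    baker_lonsdale = c(kBL = 0.15),
    korsmeyer_peppas = c(k = 45, n = 0.2329),
    hixson_crowell = c(kHC = 0.9)
  )
  for (m in names(truth)) {
    y <- eval_release_model(m, truth[[m]], tt)
    prof <- release_profile(tt, pmin(y, 110), label = m)
    fit <- fit_release_model(prof, m)
    expect_gte(fit$r_squared, 1 - 1e-8)
    expect_equal(unname(fit$params[names(truth[[m]])]),
                 unname(truth[[m]]), tolerance = 1e-4)
  }
})

test_that("power-law fit agrees with an exhaustive lattice search", {
  tt <- c(0.5, 1, 2, 3, 4, 5, 6, 8, 10)
  y <- 45 * tt^0.2329
  prof <- release_profile(tt, y)
  fit <- fit_release_model(prof, "korsmeyer_peppas")
  expect_equal(fit$n_value, 0.2329, tolerance = 1e-4)
  grid <- oracle_peppas_grid(tt, y,
                             k_grid = seq(44, 46, by = 0.05),
                             n_grid = seq(0.2, 0.27, by = 5e-4))
  expect_equal(unname(fit$params["k"]), unname(grid["k"]), tolerance = 2e-3)
  expect_equal(fit$n_value, unname(grid["n"]), tolerance = 3e-3)
})

test_that("lattice oracle and gradient fit agree on random power-law data", {
  withr::with_seed(101, {
    for (i in 1:5) {
      k_true <- runif(1, 20, 60)
      n_true <- runif(1, 0.15, 0.8)
      tt <- sort(runif(10, 0.25, 10))
      y <- pmin(k_true * tt^n_true + rnorm(10, 0, 0.5), 100)
      prof <- release_profile(tt, pmax(y, 0))
      fit <- fit_release_model(prof, "korsmeyer_peppas")
      # exhaustive neighbourhood search bracketing the gradient solution:
      # its argmin must coincide with the fit to lattice resolution
      grid <- oracle_peppas_grid(
        tt, prof$released,
        k_grid = unname(fit$params["k"]) * seq(0.85, 1.15, length.out = 181),
        n_grid = fit$n_value * seq(0.85, 1.15, length.out = 181))
      expect_equal(unname(fit$params["k"]), unname(grid["k"]),
                   tolerance = 0.01)
      expect_equal(fit$n_value, unname(grid["n"]), tolerance = 0.01)
    }
  })
})

test_that("degenerate and undersized profiles are rejected", {
  flat <- release_profile(1:5, rep(40, 5))
  expect_error(fit_release_model(flat, "higuchi"), "degenerate")
  prof <- release_profile(1:12, 20 * sqrt(1:12))
  expect_error(fit_release_model(prof, "korsmeyer_peppas",
                                 fit_window = c(0, 2)),
               "too few points")
})

test_that("model ranking puts the generating model first", {
  prof <- gen_release_profile("higuchi", c(kH = 22), times = 1:12,
                              sd = 0.5, seed = 11)
  rk <- select_release_models(prof)
  expect_s3_class(rk, "release_ranking")
  expect_identical(rk$model[1], "higuchi")
  expect_true(all(diff(rk$r_squared[rk$status == "ok"]) <= 1e-12))
  # single candidate: trivially rank 1
  one <- select_release_models(prof, models = "higuchi")
  expect_identical(one$rank, 1L)
})

test_that("power-law truth wins the ranking under moderate noise", {
  wins <- 0L
  for (s in 1:40) {
    prof <- gen_release_profile("korsmeyer_peppas", c(k = 45, n = 0.2329),
                                times = c(0.5, 1:10), sd = 2, seed = 1000 + s)
    rk <- select_release_models(prof)
    if (rk$model[1] == "korsmeyer_peppas") wins <- wins + 1L
  }
  expect_gte(wins, 36L)  # >= 90% of seeded replicates
})

test_that("failed candidates are kept with a reason, not dropped", {
  flat <- release_profile(1:6, rep(50, 6))
  rk <- suppressWarnings(
    select_release_models(flat, models = c("higuchi", "first_order")))
  expect_true(all(grepl("degenerate", rk$status)))
  expect_true(all(is.na(rk$r_squared)))
})

test_that("mechanism classification follows the exponent thresholds", {
  expect_identical(classify_mechanism(0.2329)$label, "fickian")
  # boundary is half-open: 0.45 already counts as anomalous
  expect_identical(classify_mechanism(0.45)$label, "anomalous")
  expect_identical(classify_mechanism(0.6)$label, "anomalous")
  expect_identical(classify_mechanism(0.89)$label, "case_II")
  expect_identical(classify_mechanism(1.5)$label, "super_case_II")
  expect_error(classify_mechanism(0), "positive")
  expect_error(classify_mechanism(-0.2), "positive")
})

test_that("peppas fit window rules select the documented ranges", {
  prof <- release_profile(1:12, 20 * sqrt(1:12))
  expect_equal(peppas_fit_window(prof, "first10h"), c(0, 10))
  expect_equal(peppas_fit_window(prof, "below60pct")[2],
               max(prof$times[prof$released <= 60]))
})
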