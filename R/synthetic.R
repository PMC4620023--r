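#' Default aqueous-humor sampling schedule
#'
#' The destructive-sampling schedule used throughout the package's
#' simulations: ten time points between 0.5 and 24 h post instillation,
#' dense around the absorption peak and sparse in the terminal phase.
#'
#' @return Numeric vector of hours.
#' @export
ocular_sampling_times <- function() {
  c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 12, 24)
}

#' Simulate destructive-sampling concentration data
#'
#' Draws `n_replicates` independent noisy measurements around a true
#' Bateman curve at each sampling time, emulating a destructive design in
#' which every measurement comes from a different eye. Noise is
#' multiplicative lognormal (assay coefficients of variation are
#' proportional to the measured level): each draw is
#' `truth * exp(eps)`, `eps ~ N(0, sdlog)` with
#' `sdlog = sqrt(log(1 + cv^2))`, so the truth curve is the median of the
#' noise distribution and `cv = 0` reproduces it exactly. Values below the
#' lower limit of quantification are censored to zero and counted.
#'
#' @param fit A [bateman_fit()] holding the true curve.
#' @param times Sampling times in hours (default
#'   [ocular_sampling_times()]).
#' @param n_replicates Eyes per time point (default 3).
#' @param cv Assay coefficient of variation (default 0.1).
#' @param lloq Lower limit of quantification in ug/mL (default 0.05, the
#'   bottom of a 50-1000 ng/mL calibration line); set 0 to disable.
#' @param seed Integer seed; the same seed always yields the same dataset.
#' @param arm Arm label for the resulting profile.
#'
#' @return A [conc_profile()] with replicates; the number of censored
#'   values is attached as attribute `n_censored`.
#' @export
#' @examples
#' truth <- calibrate_from_summary(0.7252, 0.1233, 51.23)
#' gen_conc_profile(truth, cv = 0.1, seed = 42)
gen_conc_profile <- function(fit, times = ocular_sampling_times(),
                             n_replicates = 3, cv = 0.1, lloq = 0.05,
                             seed = 1L, arm = "synthetic") {
  stopifnot(inherits(fit, "bateman_fit"))
  if (length(times) < 1) stop("need at least one sampling time",
                              call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  truth <- bateman_conc(fit, times)
  tt <- rep(times, each = n_replicates)
  tr <- rep(truth, each = n_replicates)
  vals <- withr::with_seed(as.integer(seed), {
    if (cv == 0) {
      tr
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      tr * exp(stats::rnorm(length(tr), 0, sdlog))
    }
  })
  censored <- lloq > 0 & vals < lloq
  vals[censored] <- 0
  out <- conc_profile(tt, vals,
                      replicate = rep(seq_len(n_replicates), length(times)),
                      arm = arm)
  attr(out, "n_censored") <- sum(censored)
  out
}

#' Biphasic burst-release curve
#'
#' Idealized release shape of a surface-loaded sustained-release
#' microsphere: an immediate burst (surface-adsorbed drug desorbing within
#' minutes) followed by a slow power-law rise towards a plateau (matrix
#' diffusion). `released(t) = burst * (1 - exp(-burst_rate * t)) +
#' (plateau - burst) * (t / t_ref)^tail_exponent`.
#'
#' @param times Hours.
#' @param burst Burst magnitude, percent (default 50).
#' @param plateau Release at `t_ref`, percent (default 90).
#' @param burst_rate Burst rate constant, 1/h (default 20: the burst is
#'   essentially complete within a quarter hour).
#' @param tail_exponent Power-law exponent of the slow phase (default 0.65).
#' @param t_ref Reference time at which the plateau is reached, hours
#'   (default 12).
#' @return Percent released at each time.
#' @export
biphasic_release <- function(times, burst = 50, plateau = 90,
                             burst_rate = 20, tail_exponent = 0.65,
                             t_ref = 12) {
  if (plateau < burst) stop("plateau must be >= burst", call. = FALSE)
  burst * (1 - exp(-burst_rate * times)) +
    (plateau - burst) * (times / t_ref)^tail_exponent
}

#' Simulate an in vitro release profile
#'
#' Generates cumulative-release data from a named release-kinetics model or
#' from the built-in `"biphasic_burst"` preset, adds additive Gaussian noise
#' (release assays report absolute percent error), clips to `[0, 100]` and
#' restores monotone non-decreasing cumulative release by isotonic
#' (least-squares monotone) projection.
#'
#' @param model A model name accepted by [eval_release_model()], or
#'   `"biphasic_burst"`.
#' @param params Named constants for the model; for the preset, any of
#'   `burst`, `plateau`, `burst_rate`, `tail_exponent`, `t_ref` (see
#'   [biphasic_release()]).
#' @param times Sampling times in hours; default hourly over 12 h.
#' @param sd Additive noise standard deviation in percent units
#'   (default 2).
#' @param seed Integer seed.
#' @param label Profile label.
#' @return A [release_profile()].
#' @export
#' @examples
#' gen_release_profile("korsmeyer_peppas", c(k = 45, n = 0.2329),
#'                     sd = 2, seed = 7)
gen_release_profile <- function(model, params = list(), times = 1:12,
                                sd = 2, seed = 1L, label = model) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  truth <- if (identical(model, "biphasic_burst")) {
    do.call(biphasic_release, c(list(times = times), as.list(params)))
  } else {
    eval_release_model(model, params, times)
  }
  vals <- withr::with_seed(as.integer(seed), {
    truth + if (sd == 0) 0 else stats::rnorm(length(truth), 0, sd)
  })
  vals <- pmin(pmax(vals, 0), 100)
  # isotonic projection: cumulative release cannot decrease
  vals <- stats::isoreg(times, vals)$yf
  release_profile(times, vals, label = label)
}
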