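#' Aqueous-humor concentration-time profile
#'
#' Container for a single treatment arm's concentration data. With a
#' destructive-sampling design each time point comes from independent eyes;
#' replicate measurements are pooled to their per-time mean (the analysis
#' level used throughout the package) while the raw replicates are retained.
#'
#' @param times Hours post instillation. With `replicate` supplied, times
#'   may repeat (long format); otherwise they must be unique.
#' @param concentrations Drug concentration in ug/mL, `>= 0`.
#' @param replicate Optional replicate (eye) identifier per row.
#' @param arm Treatment-arm label.
#'
#' @return Object of class `conc_profile`: `times` (sorted, unique),
#'   `concentrations` (per-time means), `n_per_point`, `arm`, and
#'   `replicates` (raw long-format data frame or `NULL`).
#' @export
conc_profile <- function(times, concentrations, replicate = NULL, arm = "") {
  if (!is.numeric(times) || !is.numeric(concentrations)) {
    stop("`times` and `concentrations` must be numeric", call. = FALSE)
  }
  if (length(times) != length(concentrations)) {
    stop("`times` and `concentrations` must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(concentrations) ||
      any(!is.finite(c(times, concentrations)))) {
    stop("concentration profile values must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (!is.null(replicate)) {
    if (length(replicate) != length(times)) {
      stop("`replicate` must match the data length", call. = FALSE)
    }
    key <- paste(times, replicate)
    if (anyDuplicated(key)) {
      stop("duplicate (time, replicate) pairs", call. = FALSE)
    }
    raw <- data.frame(time_h = times, conc_ug_ml = concentrations,
                      replicate = replicate, stringsAsFactors = FALSE)
    raw <- raw[order(raw$time_h, raw$replicate), , drop = FALSE]
    rownames(raw) <- NULL
    tt <- sort(unique(times))
    cc <- vapply(tt, function(h) mean(concentrations[times == h]), numeric(1))
    nn <- vapply(tt, function(h) sum(times == h), integer(1))
  } else {
    if (anyDuplicated(times)) {
      stop("duplicate times; supply `replicate` ids for repeated sampling",
           call. = FALSE)
    }
    ord <- order(times)
    tt <- times[ord]
    cc <- concentrations[ord]
    nn <- rep(1L, length(tt))
    raw <- NULL
  }
  structure(
    list(times = as.numeric(tt), concentrations = as.numeric(cc),
         n_per_point = nn, arm = as.character(arm), replicates = raw),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat("<conc_profile>", if (nzchar(x$arm)) x$arm else "(unlabelled)", "\n")
  cat(sprintf("  %d time points over %.3g-%.3g h, Cmax(obs) = %.4g ug/mL\n",
              length(x$times), min(x$times), max(x$times),
              max(x$concentrations)))
  if (!is.null(x$replicates)) {
    cat(sprintf("  replicates: %d measurements (n = %s per point)\n",
                nrow(x$replicates),
                paste(unique(x$n_per_point), collapse = "/")))
  }
  invisible(x)
}

#' One-compartment open-model (Bateman) parameter set
#'
#' Bundles the amplitude and the absorption / elimination rate constants of
#' the Bateman curve `C(t) = A * (exp(-Ke*t) - exp(-Ka*t))` together with the
#' derived peak time, peak concentration and terminal half-life. When the
#' fitted `Ka` is smaller than `Ke` the curve is in the flip-flop regime
#' (the terminal slope reflects absorption); this is flagged, never silently
#' relabelled.
#'
#' @param A Amplitude in ug/mL (`>= 0`; zero gives a degenerate flat curve).
#' @param ka Apparent first-order absorption rate constant, 1/h.
#' @param ke Terminal (elimination) rate constant, 1/h.
#' @param terminal_points_used Number of points behind the terminal slope
#'   estimate, if any.
#' @param source Free-text provenance note (e.g. `"fit"` or `"summary"`).
#'
#' @return Object of class `bateman_fit` with elements `A`, `ka`, `ke`,
#'   `tmax`, `cmax`, `t_half`, `flip_flop`, `terminal_points_used`, `source`.
#' @export
#' @examples
#' fit <- bateman_fit(A = 88.7, ka = 0.7252, ke = 0.1233)
#' fit$tmax
bateman_fit <- function(A, ka, ke, terminal_points_used = NA_integer_,
                        source = "manual") {
  if (!all(is.finite(c(A, ka, ke)))) stop("non-finite parameters",
                                          call. = FALSE)
  if (ka <= 0 || ke <= 0) stop("ka and ke must be > 0", call. = FALSE)
  if (A < 0) stop("amplitude must be >= 0", call. = FALSE)
  tc <- tmax_cmax(ka, ke, A)
  structure(
    list(A = A, ka = ka, ke = ke,
         tmax = tc$tmax, cmax = tc$cmax, t_half = log(2) / ke,
         flip_flop = ka < ke,
         terminal_points_used = terminal_points_used,
         source = source),
    class = "bateman_fit"
  )
}

#' @export
print.bateman_fit <- function(x, ...) {
  cat(sprintf(
    "<bateman_fit> A = %.4g ug/mL, Ka = %.4g /h, Ke = %.4g /h (%s)\n",
    x$A, x$ka, x$ke, x$source))
  cat(sprintf("  Tmax = %.4g h, Cmax = %.4g ug/mL, t1/2 = %.4g h%s\n",
              x$tmax, x$cmax, x$t_half,
              if (isTRUE(x$flip_flop)) "  [flip-flop: Ka < Ke]" else ""))
  invisible(x)
}

.bateman_degenerate <- function(ka, ke) abs(ka - ke) <= 1e-10 * max(ka, ke)

#' Evaluate the Bateman concentration curve
#'
#' `C(t) = A * (exp(-Ke*t) - exp(-Ka*t))`, with `C(0) = 0` and `C -> 0` as
#' `t -> Inf`. At the degenerate point `Ka = Ke` the curve is evaluated in
#' its limiting reparameterized form `A * Ke * t * exp(-Ke*t)` (the limit of
#' the difference quotient as the two rates coalesce, with `A` absorbing the
#' `1/(Ka - Ke)` scale).
#'
#' @param fit A [bateman_fit()].
#' @param t Times in hours, `>= 0`.
#' @return Concentrations in ug/mL.
#' @export
bateman_conc <- function(fit, t) {
  stopifnot(inherits(fit, "bateman_fit"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (.bateman_degenerate(fit$ka, fit$ke)) {
    fit$A * fit$ke * t * exp(-fit$ke * t)
  } else {
    fit$A * (exp(-fit$ke * t) - exp(-fit$ka * t))
  }
}

#' Peak time and peak concentration of a Bateman curve
#'
#' Closed forms: `Tmax = log(Ka/Ke) / (Ka - Ke)` (limit `1/Ke` when
#' `Ka = Ke`) and `Cmax = C(Tmax)`.
#'
#' @param ka,ke Rate constants, 1/h, `> 0`.
#' @param A Amplitude, ug/mL.
#' @return List with `tmax` (h) and `cmax` (ug/mL).
#' @export
#' @examples
#' tmax_cmax(0.7252, 0.1233, 88.7)
tmax_cmax <- function(ka, ke, A) {
  if (ka <= 0 || ke <= 0) stop("ka and ke must be > 0", call. = FALSE)
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (.bateman_degenerate(ka, ke)) {
    tmax <- 1 / ke
    cmax <- A * ke * tmax * exp(-ke * tmax)
  } else {
    tmax <- log(ka / ke) / (ka - ke)
    cmax <- A * (exp(-ke * tmax) - exp(-ka * tmax))
  }
  list(tmax = tmax, cmax = cmax)
}

#' Reconstruct a Bateman curve from published summary parameters
#'
#' Given the rate constants and the peak concentration as printed in a
#' pharmacokinetics summary table, solves for the amplitude
#' `A = Cmax / (exp(-Ke*Tmax) - exp(-Ka*Tmax))` with `Tmax` from its closed
#' form, so that the reconstructed curve reproduces the printed `Cmax`
#' exactly at its peak. This makes curve-level quantities (time above a
#' threshold, AUC above a threshold, dosing interval, multi-dose
#' superposition) computable when only the summary table is available.
#'
#' The rate constants printed in such tables are not always mutually
#' consistent with the printed half-life; `ke` here is taken at face value,
#' and a caller wishing to use the half-life convention should pass
#' `ke = log(2) / t_half` explicitly.
#'
#' @param ka,ke Rate constants, 1/h, `> 0`, `ka != ke`.
#' @param cmax Peak concentration, ug/mL, `>= 0`.
#' @return A [bateman_fit()] with `source = "summary"`.
#' @export
#' @examples
#' calibrate_from_summary(ka = 0.7252, ke = 0.1233, cmax = 51.23)
calibrate_from_summary <- function(ka, ke, cmax) {
  if (ka <= 0 || ke <= 0) stop("ka and ke must be > 0", call. = FALSE)
  if (cmax < 0) stop("cmax must be >= 0", call. = FALSE)
  if (.bateman_degenerate(ka, ke)) {
    tmax <- 1 / ke
    A <- cmax / (ke * tmax * exp(-ke * tmax))
  } else {
    tmax <- log(ka / ke) / (ka - ke)
    A <- cmax / (exp(-ke * tmax) - exp(-ka * tmax))
  }
  bateman_fit(A = A, ka = ka, ke = ke, source = "summary")
}

#' Analytic area under a Bateman curve
#'
#' Closed-form `AUC` between two times; over `[0, Inf)` this is
#' `A * (1/Ke - 1/Ka)`.
#'
#' @param fit A [bateman_fit()].
#' @param lower,upper Integration bounds in hours (`upper = Inf` allowed).
#' @return AUC in h*ug/mL.
#' @export
bateman_auc <- function(fit, lower = 0, upper = Inf) {
  stopifnot(inherits(fit, "bateman_fit"), lower >= 0, upper >= lower)
  ee <- function(k, t) if (is.infinite(t)) 0 else exp(-k * t)
  if (.bateman_degenerate(fit$ka, fit$ke)) {
    antider <- function(t) {
      if (is.infinite(t)) return(0)
      -fit$A * (t + 1 / fit$ke) * exp(-fit$ke * t)
    }
    antider(upper) - antider(lower)
  } else {
    fit$A * ((ee(fit$ke, lower) - ee(fit$ke, upper)) / fit$ke -
               (ee(fit$ka, lower) - ee(fit$ka, upper)) / fit$ka)
  }
}

#' Terminal elimination rate from the log-linear tail
#'
#' Estimates `Ke` as minus the slope of `log(concentration)` vs time over
#' the last `n_terminal` strictly positive concentrations (values censored
#' to zero, e.g. below the assay quantification limit, are excluded before
#' the window is taken). A non-negative slope (concentrations still rising)
#' is flagged as `"non-terminal phase"` rather than silently negated.
#'
#' @param profile A [conc_profile()] (per-time means are used).
#' @param n_terminal Number of tail points, `>= 2` (default 3).
#'
#' @return Object of class `terminal_fit`: list with `ke` (1/h),
#'   `r_squared` of the log-linear regression, `log_intercept` (the
#'   back-extrapolated `log` concentration at `t = 0`), `n_points`, `times`
#'   used and `flag` (`NA` or `"non-terminal phase"`).
#' @export
fit_terminal_ke <- function(profile, n_terminal = 3) {
  stopifnot(inherits(profile, "conc_profile"))
  if (n_terminal < 2) stop("n_terminal must be >= 2", call. = FALSE)
  pos <- profile$concentrations > 0
  if (sum(pos) < 2) {
    stop("need at least 2 strictly positive concentrations for the ",
         "terminal fit", call. = FALSE)
  }
  tt <- profile$times[pos]
  cc <- profile$concentrations[pos]
  idx <- seq(max(1L, length(tt) - n_terminal + 1L), length(tt))
  tt <- tt[idx]
  cc <- cc[idx]
  fit <- stats::lm(log(cc) ~ tt)
  slope <- unname(stats::coef(fit)[2])
  lc <- log(cc)
  sst <- sum((lc - mean(lc))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(ke = -slope, r_squared = r2,
         log_intercept = unname(stats::coef(fit)[1]),
         n_points = length(tt), times = tt,
         flag = if (slope >= 0) "non-terminal phase" else NA_character_),
    class = "terminal_fit"
  )
}

#' Fit the Bateman curve to a concentration profile
#'
#' Nonlinear least squares on `(A, Ka, Ke)` against the per-time mean
#' concentrations, by Levenberg-Marquardt with positivity constraints.
#' Starting values come from the terminal log-linear slope (`Ke` and the
#' back-extrapolated intercept for `A`) and from the method of residuals
#' (feathering) on the pre-peak points for `Ka`, falling back to `5 * Ke`
#' when feathering is not possible; a fixed ladder of perturbed starts
#' guards against local minima. A fitted `Ka < Ke` sets the flip-flop flag;
#' with `absorption_limited = TRUE` the caller asserts absorption-limited
#' kinetics and the two rate labels are swapped instead.
#'
#' @param profile A [conc_profile()] with at least 4 time points spanning
#'   both the rising and the terminal phase.
#' @param n_terminal Tail points for the initial `Ke` (default 3).
#' @param absorption_limited Assert that the larger exponent is `Ka`
#'   (default `FALSE`: report the flip-flop flag, do not relabel).
#'
#' @return A [bateman_fit()] with `source = "fit"`.
#' @export
fit_bateman <- function(profile, n_terminal = 3, absorption_limited = FALSE) {
  stopifnot(inherits(profile, "conc_profile"))
  t <- profile$times
  y <- profile$concentrations
  if (length(t) < 4) stop("need at least 4 time points", call. = FALSE)
  if (all(y == 0)) stop("all-zero profile", call. = FALSE)
  if (sum(y > 0) < 2) {
    stop("need at least 2 positive concentrations", call. = FALSE)
  }

  term <- fit_terminal_ke(profile, n_terminal = n_terminal)
  ke0 <- if (term$ke > 0) term$ke else 0.1
  A0 <- exp(term$log_intercept)
  if (!is.finite(A0) || A0 <= 0) A0 <- max(y)

  # method of residuals on pre-peak points: log(A0*exp(-ke0*t) - C) vs t
  ipk <- which.max(y)
  ka0 <- NA_real_
  if (ipk > 2) {
    tp <- t[seq_len(ipk - 1)]
    rp <- A0 * exp(-ke0 * tp) - y[seq_len(ipk - 1)]
    ok <- rp > 0
    if (sum(ok) >= 2) {
      sl <- unname(stats::coef(stats::lm(log(rp[ok]) ~ tp[ok]))[2])
      if (is.finite(sl) && -sl > ke0) ka0 <- -sl
    }
  }
  if (!is.finite(ka0)) ka0 <- 5 * ke0

  resid_fn <- function(p) {
    y - p[1] * (exp(-p[3] * t) - exp(-p[2] * t))
  }
  best <- NULL
  best_sse <- Inf
  for (f in c(1, 0.5, 2, 0.2, 5)) {
    p0 <- c(A = max(A0, 1e-6), ka = max(ka0 * f, 1e-6), ke = max(ke0, 1e-6))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = rep(1e-9, 3),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !(res$info %in% 1:4)) next
    sse <- sum(res$fvec^2)
    if (sse < best_sse) {
      best <- res
      best_sse <- sse
    }
  }
  if (is.null(best)) stop("Bateman fit did not converge", call. = FALSE)
  p <- best$par
  A <- unname(p[1]); ka <- unname(p[2]); ke <- unname(p[3])
  if (absorption_limited && ka < ke) {
    tmp <- ka; ka <- ke; ke <- tmp
  }
  out <- bateman_fit(A = A, ka = ka, ke = ke,
                     terminal_points_used = term$n_points, source = "fit")
  out$sse <- best_sse
  out
}
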