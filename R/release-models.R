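#' @keywords internal
"%||%" <- function(a, b) if (is.null(a)) b else a

#' Names of the supported release-kinetics models
#'
#' The five classical dissolution models compared by the package, in the
#' conventional order: first order, Higuchi square-root, Baker-Lonsdale
#' (single-exponential spherical-matrix form), Korsmeyer-Peppas power law and
#' Hixson-Crowell cube-root. Two further variants are available to
#' [eval_release_model()] and [fit_release_model()] but are not part of the
#' default candidate set: `"baker_lonsdale_classical"` (the implicit
#' `3/2 * (1 - (1 - Q/Qinf)^(2/3)) - Q/Qinf = k * t` form) and
#' `"peppas_two_term"` (power law plus a second-order `t^(2n)` term with
#' lumped geometric constants).
#'
#' @return Character vector of model names.
#' @export
release_model_names <- function() {
  c("first_order", "higuchi", "baker_lonsdale", "korsmeyer_peppas",
    "hixson_crowell")
}

# free parameters fitted for each model (q0 / qinf are fixed scale inputs)
.release_par_names <- function(model) {
  switch(model,
    first_order = "k1",
    higuchi = "kH",
    baker_lonsdale = "kBL",
    korsmeyer_peppas = c("k", "n"),
    hixson_crowell = "kHC",
    peppas_two_term = c("a", "b", "n"),
    baker_lonsdale_classical = "k",
    stop("unknown release model: ", model, call. = FALSE)
  )
}

# release fraction x = Q/Qinf solving the classical Baker-Lonsdale implicit
# equation 3/2*(1-(1-x)^(2/3)) - x = k*t; complete release at k*t >= 1/2
.bl_classical_fraction <- function(kt) {
  vapply(kt, function(z) {
    if (z <= 0) return(0)
    if (z >= 0.5) return(1)
    f <- function(x) 1.5 * (1 - (1 - x)^(2 / 3)) - x - z
    stats::uniroot(f, c(0, 1 - 1e-12), tol = 1e-12)$root
  }, numeric(1))
}

#' Evaluate a release-kinetics model
#'
#' Computes the model-predicted cumulative percent released at the given
#' times. All models are expressed on the *released* axis so that they are
#' directly comparable; the first-order and Hixson-Crowell equations are
#' classically written for the amount *remaining*, and `form = "remaining"`
#' returns that convention (`q0 - released`).
#'
#' Model forms (Q = percent released, t in hours):
#' * `first_order`: `Q = q0 * (1 - exp(-k1 * t))` (remaining
#'   `q0 * exp(-k1 * t)`).
#' * `higuchi`: `Q = kH * sqrt(t)`.
#' * `baker_lonsdale`: `Q = qinf * (1 - (6/pi^2) * exp(-kBL * t))` --- the
#'   single-exponential spherical-matrix form with the lumped constant
#'   `kBL = pi^2 * D / r^2` (diffusivity and radius are not separately
#'   identifiable).
#' * `korsmeyer_peppas`: `Q = k * t^n`, the one-term power law.
#' * `hixson_crowell`: remaining`^(1/3) = q0^(1/3) - kHC * t`, i.e.
#'   `Q = q0 - (q0^(1/3) - kHC * t)^3`, clamped at complete release.
#' * `peppas_two_term`: `Q = q0 + a * t^n + b * t^(2n)` with lumped
#'   geometric constants.
#' * `baker_lonsdale_classical`: the implicit cube-root matrix equation
#'   (see [release_model_names()]); solved numerically per time point.
#'
#' @param model Model name (see [release_model_names()]).
#' @param params Named numeric vector or list of model constants. Optional
#'   entries `q0` (initial/total amount, default 100 percent) and `qinf`
#'   (release at infinite time, default 100 percent) set the scale.
#' @param times Numeric vector of times in hours, `>= 0`.
#' @param form `"released"` (default) or `"remaining"`.
#'
#' @return Numeric vector of predicted cumulative percent released (or
#'   remaining) at each time.
#' @export
#' @examples
#' eval_release_model("higuchi", c(kH = 20), times = 4)       # 40
#' eval_release_model("korsmeyer_peppas", c(k = 45, n = 0.2329), times = 1:4)
eval_release_model <- function(model, params, times,
                               form = c("released", "remaining")) {
  form <- match.arg(form)
  params <- as.list(params)
  if (!is.numeric(times) || anyNA(times)) {
    stop("`times` must be numeric and non-missing", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  need <- .release_par_names(model)
  missing_par <- setdiff(need, names(params))
  if (length(missing_par)) {
    stop("missing model constant(s) for ", model, ": ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  # rate constants and the release exponent must be non-negative; the
  # two-term Peppas shape constants a, b may take either sign
  nonneg <- intersect(names(params), c("k1", "kH", "kBL", "k", "kHC", "n"))
  bad <- nonneg[vapply(nonneg, function(p) params[[p]] < 0, logical(1))]
  if (length(bad)) {
    stop("negative model constant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("n" %in% need && params$n <= 0) {
    stop("release exponent n must be > 0", call. = FALSE)
  }
  q0 <- params$q0 %||% 100
  qinf <- params$qinf %||% 100
  released <- switch(model,
    first_order = q0 * (1 - exp(-params$k1 * times)),
    higuchi = params$kH * sqrt(times),
    baker_lonsdale = qinf * (1 - (6 / pi^2) * exp(-params$kBL * times)),
    korsmeyer_peppas = params$k * times^params$n,
    hixson_crowell = q0 - pmax(q0^(1 / 3) - params$kHC * times, 0)^3,
    peppas_two_term = q0 + params$a * times^params$n +
      params$b * times^(2 * params$n),
    baker_lonsdale_classical = qinf * .bl_classical_fraction(params$k * times)
  )
  if (form == "released") released else q0 - released
}

# deterministic linearized starting values for the nonlinear fits
.release_init <- function(model, t, y, q0, qinf) {
  eps <- 1e-6
  pos <- t > 0 & y > 0
  switch(model,
    first_order = {
      rem <- pmax(q0 - y, eps)
      c(k1 = max(-unname(stats::coef(stats::lm(log(rem) ~ t))[2]), 1e-3))
    },
    higuchi = c(kH = max(sum(y * sqrt(t)) / max(sum(t), eps), 1e-3)),
    baker_lonsdale = {
      gap <- pmax(qinf - y, eps)
      c(kBL = max(-unname(stats::coef(stats::lm(log(gap) ~ t))[2]), 1e-3))
    },
    korsmeyer_peppas = {
      if (sum(pos) >= 2) {
        co <- stats::coef(stats::lm(log(y[pos]) ~ log(t[pos])))
        c(k = max(exp(unname(co[1])), 1e-3), n = min(max(unname(co[2]), 0.05), 3))
      } else c(k = max(y), n = 0.5)
    },
    hixson_crowell = {
      z <- q0^(1 / 3) - pmax(q0 - y, 0)^(1 / 3)
      c(kHC = max(sum(z * t) / max(sum(t^2), eps), 1e-4))
    },
    peppas_two_term = {
      one <- .release_init("korsmeyer_peppas", t, y, q0, qinf)
      c(a = unname(one["k"]), b = 1e-3, n = unname(one["n"]))
    },
    baker_lonsdale_classical = {
      x <- pmin(pmax(y / qinf, 0), 1 - 1e-9)
      kt <- 1.5 * (1 - (1 - x)^(2 / 3)) - x
      c(k = max(mean(kt[t > 0] / t[t > 0]), 1e-4))
    }
  )
}

#' Fit one release-kinetics model to a profile
#'
#' Least-squares fit of the named model to cumulative release data by
#' Levenberg-Marquardt with box constraints at zero (negative rate constants
#' are rejected by construction). The optimizer is started from a
#' deterministic linearized guess (log-linear regression of remaining vs
#' time for first order, log-log for the power law, release vs `sqrt(t)`
#' for Higuchi, ...) plus a fixed ladder of multiplicative perturbations of
#' that guess; the best converged start by SSE wins.
#'
#' The coefficient of determination is the degrees-of-freedom-free
#' `R^2 = 1 - SSE / SST` with SST about the mean of the fitted window.
#'
#' @param profile A [release_profile()].
#' @param model Model name (see [eval_release_model()]).
#' @param fit_window Optional numeric `c(t_min, t_max)`; only points inside
#'   the window are fitted. Default: the whole profile.
#' @param q0,qinf Fixed scale constants (percent), defaults 100.
#' @param n_starts Number of optimizer starts (first is the linearized
#'   guess), default 5.
#'
#' @return An object of class `release_fit`: list with `model`, `params`
#'   (named numeric), `r_squared`, `n_value` (release exponent, `NA` for
#'   models without one), `fit_window`, `sse` and `n_points`.
#' @export
#' @examples
#' prof <- release_profile(1:12, 20 * sqrt(1:12))
#' fit_release_model(prof, "higuchi")$params
fit_release_model <- function(profile, model, fit_window = NULL,
                              q0 = 100, qinf = 100, n_starts = 5) {
  stopifnot(inherits(profile, "release_profile"))
  .release_par_names(model) # validates the name
  w <- fit_window %||% range(profile$times)
  keep <- profile$times >= w[1] & profile$times <= w[2]
  t <- profile$times[keep]
  y <- profile$released[keep]
  npar <- length(.release_par_names(model))
  if (length(t) < max(3L, npar + 1L)) {
    stop("too few points in fit window for model ", model, call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate profile: constant release values", call. = FALSE)
  }

  resid_fn <- function(p) {
    pr <- as.list(p)
    pr$q0 <- q0
    pr$qinf <- qinf
    y - eval_release_model(model, pr, t)
  }
  init <- .release_init(model, t, y, q0, qinf)
  # fixed perturbation ladder around the linearized guess
  ladder <- c(1, 0.5, 2, 0.25, 4, 0.8, 1.25)[seq_len(max(1L, n_starts))]
  best <- NULL
  best_sse <- Inf
  failures <- character(0)
  for (f in ladder) {
    p0 <- pmax(init * f, 1e-8)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = rep(1e-9, npar),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    sse <- sum(res$fvec^2)
    if (res$info %in% 1:4 && sse < best_sse) {
      best <- res
      best_sse <- sse
    }
  }
  if (is.null(best)) {
    stop("release model fit did not converge for ", model,
         if (length(failures)) paste0(" (", failures[1], ")"), call. = FALSE)
  }
  pars <- stats::setNames(as.numeric(best$par), names(init))
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - best_sse / sst
  structure(
    list(
      model = model,
      params = pars,
      r_squared = min(r2, 1),
      n_value = if ("n" %in% names(pars)) unname(pars["n"]) else NA_real_,
      fit_window = c(t_min = min(t), t_max = max(t)),
      sse = best_sse,
      n_points = length(t),
      q0 = q0, qinf = qinf
    ),
    class = "release_fit"
  )
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> %s: R^2 = %.6f\n", x$model, x$r_squared))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Fit window for the Korsmeyer-Peppas exponent
#'
#' The power-law exponent is conventionally estimated either on the early
#' portion of the study (first 10 hours) or on the portion below 60 percent
#' cumulative release. Both conventions are available; the early-time window
#' is the package default for ranking.
#'
#' @param profile A [release_profile()].
#' @param rule `"first10h"` or `"below60pct"`.
#' @param t_cap Hours for the early-time rule (default 10).
#' @param release_cap Percent for the fractional-release rule (default 60).
#'
#' @return Numeric `c(t_min, t_max)` usable as a `fit_window`.
#' @export
peppas_fit_window <- function(profile, rule = c("first10h", "below60pct"),
                              t_cap = 10, release_cap = 60) {
  stopifnot(inherits(profile, "release_profile"))
  rule <- match.arg(rule)
  if (rule == "first10h") {
    c(0, t_cap)
  } else {
    ok <- profile$released <= release_cap
    if (!any(ok)) stop("no points below the release cap", call. = FALSE)
    c(0, max(profile$times[ok]))
  }
}

#' Fit and rank candidate release models
#'
#' Fits every candidate model to the profile and ranks the results by
#' descending `R^2`, breaking ties in favour of the model with fewer fitted
#' parameters. Models that fail to fit are kept in the table with their
#' error message and rank after all successful fits.
#'
#' The Korsmeyer-Peppas model (and its two-term variant) is fitted on the
#' early-time window returned by [peppas_fit_window()] unless an explicit
#' `fit_window` is supplied, matching the convention that the power-law
#' exponent describes the first part of the release curve.
#'
#' @param profile A [release_profile()].
#' @param models Character vector of candidate model names (default: the
#'   five classical models).
#' @param fit_window Optional window applied to every model.
#' @param peppas_window Window used for the power-law models when
#'   `fit_window` is `NULL`; default `c(0, 10)` hours.
#' @param ... Passed to [fit_release_model()].
#'
#' @return An object of class `release_ranking`: a data frame with columns
#'   `model`, `r_squared`, `n_value`, `n_params`, `status`, `rank`, with the
#'   full `release_fit` objects in `attr(, "fits")`.
#' @export
select_release_models <- function(profile, models = release_model_names(),
                                  fit_window = NULL, peppas_window = c(0, 10),
                                  ...) {
  stopifnot(inherits(profile, "release_profile"))
  if (length(models) < 1L) stop("need at least one candidate model",
                                call. = FALSE)
  fits <- vector("list", length(models))
  names(fits) <- models
  status <- character(length(models))
  for (i in seq_along(models)) {
    m <- models[i]
    fw <- fit_window
    if (is.null(fw) && m %in% c("korsmeyer_peppas", "peppas_two_term")) {
      fw <- peppas_window
    }
    res <- tryCatch(fit_release_model(profile, m, fit_window = fw, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      status[i] <- "ok"
    }
  }
  r2 <- vapply(fits, function(f) if (is.null(f)) -Inf else f$r_squared,
               numeric(1))
  np <- vapply(models, function(m) length(.release_par_names(m)), integer(1))
  ord <- order(-r2, np)
  tab <- data.frame(
    model = models[ord],
    r_squared = ifelse(is.finite(r2[ord]), r2[ord], NA_real_),
    n_value = vapply(fits[ord], function(f) {
      if (is.null(f)) NA_real_ else f$n_value
    }, numeric(1)),
    n_params = np[ord],
    status = status[ord],
    rank = seq_along(models),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(tab, fits = fits[ord], class = c("release_ranking", "data.frame"))
}

#' Default mechanism-classification thresholds
#'
#' Threshold set for interpreting the Korsmeyer-Peppas release exponent from
#' spherical matrices: `n < 0.45` Fickian diffusion, `0.45 <= n < 0.89`
#' anomalous (non-Fickian) transport, `n = 0.89` (within `tol`) case-II
#' relaxation-controlled transport, `n > 0.89` super case-II. Boundaries are
#' half-open: an exponent exactly at 0.45 is classified anomalous.
#'
#' @param fickian_max Upper bound (exclusive) for Fickian diffusion.
#' @param case2 Case-II exponent.
#' @param tol Absolute tolerance for the case-II point.
#' @return Named list with the three values.
#' @export
mechanism_thresholds <- function(fickian_max = 0.45, case2 = 0.89,
                                 tol = 1e-6) {
  list(fickian_max = fickian_max, case2 = case2, tol = tol)
}

#' Classify the drug-release mechanism from the release exponent
#'
#' @param n_value Fitted Korsmeyer-Peppas exponent, `> 0`.
#' @param thresholds Threshold set, see [mechanism_thresholds()].
#'
#' @return Object of class `mechanism_label`: list with `label` (one of
#'   `"fickian"`, `"anomalous"`, `"case_II"`, `"super_case_II"`), `n_value`
#'   and the `threshold_set` used.
#' @export
#' @examples
#' classify_mechanism(0.2329)$label  # "fickian"
classify_mechanism <- function(n_value, thresholds = mechanism_thresholds()) {
  if (!is.numeric(n_value) || length(n_value) != 1L || !is.finite(n_value) ||
      n_value <= 0) {
    stop("release exponent must be a single positive number", call. = FALSE)
  }
  label <- if (abs(n_value - thresholds$case2) <= thresholds$tol) {
    "case_II"
  } else if (n_value < thresholds$fickian_max) {
    "fickian"
  } else if (n_value < thresholds$case2) {
    "anomalous"
  } else {
    "super_case_II"
  }
  structure(list(label = label, n_value = n_value,
                 threshold_set = thresholds),
            class = "mechanism_label")
}

#' @export
print.mechanism_label <- function(x, ...) {
  cat(sprintf("<mechanism_label> n = %.4g -> %s\n", x$n_value, x$label))
  invisible(x)
}
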