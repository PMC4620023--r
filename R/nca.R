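#' Linear trapezoidal AUC over an observed profile
#'
#' Area under the concentration-time curve by the linear trapezoidal rule
#' over consecutive observed points, with linear interpolation at the
#' window cut points. For topical instillation the drug is absent before
#' dosing, so a virtual `(0 h, 0 ug/mL)` anchor is prepended when the first
#' sample is later than zero (`anchor_zero = TRUE`, the default).
#'
#' @param profile A [conc_profile()] (per-time means are used), or a
#'   numeric vector of times if `conc` is given.
#' @param t_start,t_end Integration window in hours; defaults to the full
#'   observed range (including the virtual anchor). Must lie within the
#'   observed range.
#' @param anchor_zero Prepend a `(0, 0)` point when the profile starts
#'   after time zero.
#' @param conc Concentrations when `profile` is a plain time vector.
#'
#' @return AUC in h*ug/mL.
#' @export
#' @examples
#' trapezoidal_auc(c(0, 24), conc = c(1, 1))      # 24
#' trapezoidal_auc(c(0, 2), conc = c(0, 10))      # 10
trapezoidal_auc <- function(profile, t_start = NULL, t_end = NULL,
                            anchor_zero = TRUE, conc = NULL) {
  if (inherits(profile, "conc_profile")) {
    tt <- profile$times
    cc <- profile$concentrations
  } else {
    if (is.null(conc)) stop("supply `conc` with a plain time vector",
                            call. = FALSE)
    ord <- order(profile)
    tt <- as.numeric(profile)[ord]
    cc <- as.numeric(conc)[ord]
  }
  if (anchor_zero && tt[1] > 0) {
    tt <- c(0, tt)
    cc <- c(0, cc)
  }
  t_start <- t_start %||% tt[1]
  t_end <- t_end %||% tt[length(tt)]
  if (t_end < t_start) stop("empty integration window", call. = FALSE)
  if (t_start < tt[1] || t_end > tt[length(tt)]) {
    stop("integration window outside the observed range", call. = FALSE)
  }
  if (t_end == t_start) return(0)
  c_start <- stats::approx(tt, cc, xout = t_start)$y
  c_end <- stats::approx(tt, cc, xout = t_end)$y
  inside <- tt > t_start & tt < t_end
  tw <- c(t_start, tt[inside], t_end)
  cw <- c(c_start, cc[inside], c_end)
  sum(diff(tw) * (cw[-length(cw)] + cw[-1]) / 2)
}

#' Extrapolate an AUC to infinite time
#'
#' Standard log-linear tail extrapolation:
#' `AUC(0, Inf) = AUC(0, tlast) + Clast / Ke`.
#'
#' @param auc_0_tlast AUC up to the last observation, h*ug/mL.
#' @param clast Concentration at the last observation, ug/mL, `>= 0`.
#' @param ke Terminal rate constant, 1/h, `> 0`.
#' @return AUC to infinity, h*ug/mL.
#' @export
#' @examples
#' extrapolate_auc_inf(607.187, 4.677, 0.1233)
extrapolate_auc_inf <- function(auc_0_tlast, clast, ke) {
  if (!is.numeric(ke) || ke <= 0) stop("ke must be > 0", call. = FALSE)
  if (clast < 0) stop("clast must be >= 0", call. = FALSE)
  if (auc_0_tlast < 0) stop("auc must be >= 0", call. = FALSE)
  auc_0_tlast + clast / ke
}

#' Relative bioavailability of a test vs a reference formulation
#'
#' Dose-normalized AUC ratio:
#' `(AUC_test * Dose_ref) / (AUC_ref * Dose_test)`.
#'
#' @param auc_test,auc_ref AUCs, h*ug/mL, `> 0`.
#' @param dose_test,dose_ref Administered doses (any common unit), `> 0`.
#' @return Unitless fold ratio.
#' @export
#' @examples
#' relative_bioavailability(607.187, 1, 121.634, 1)  # ~4.99
relative_bioavailability <- function(auc_test, dose_test, auc_ref, dose_ref) {
  vals <- c(auc_test, dose_test, auc_ref, dose_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all AUCs and doses must be positive", call. = FALSE)
  }
  (auc_test * dose_ref) / (auc_ref * dose_test)
}

#' Non-compartmental analysis of a concentration profile
#'
#' Observed peak, trapezoidal AUC to the last observation, and the
#' extrapolated AUC to infinity. `AUC(0, tlast)` is computed on the observed
#' means (never on a fitted curve). The extrapolation tail `Clast / Ke`
#' defaults to the last observed positive concentration; with
#' `clast = "predicted"` the model-predicted concentration at `tlast` from a
#' supplied [bateman_fit()] is used instead, which is the convention needed
#' to reproduce a summary table's `AUC(0, Inf)` when the observed tail value
#' is unpublished.
#'
#' @param profile A [conc_profile()].
#' @param ke Terminal rate constant; when `NULL`, estimated by
#'   [fit_terminal_ke()] with `n_terminal` points.
#' @param n_terminal Tail points for the internal `Ke` estimate.
#' @param clast `"observed"` (default) or `"predicted"`.
#' @param fit A [bateman_fit()], required for `clast = "predicted"`.
#' @param anchor_zero See [trapezoidal_auc()].
#'
#' @return Object of class `nca_result`: list with `auc_0_tlast`,
#'   `auc_0_inf`, `clast`, `cmax_obs`, `tmax_obs`, `tlast`,
#'   `extrapolated_fraction`, `ke_used` and `clast_method`.
#' @export
nca <- function(profile, ke = NULL, n_terminal = 3,
                clast = c("observed", "predicted"), fit = NULL,
                anchor_zero = TRUE) {
  stopifnot(inherits(profile, "conc_profile"))
  clast_method <- match.arg(clast)
  tt <- profile$times
  cc <- profile$concentrations
  ipk <- which.max(cc)
  tlast <- tt[length(tt)]
  auc_tlast <- trapezoidal_auc(profile, anchor_zero = anchor_zero)
  if (is.null(ke)) ke <- fit_terminal_ke(profile, n_terminal)$ke
  clast_val <- if (clast_method == "predicted") {
    if (is.null(fit)) stop("`fit` required for clast = \"predicted\"",
                           call. = FALSE)
    bateman_conc(fit, tlast)
  } else {
    pos <- cc > 0
    if (any(pos)) cc[max(which(pos))] else 0
  }
  auc_inf <- extrapolate_auc_inf(auc_tlast, clast_val, ke)
  structure(
    list(auc_0_tlast = auc_tlast, auc_0_inf = auc_inf, clast = clast_val,
         cmax_obs = cc[ipk], tmax_obs = tt[ipk], tlast = tlast,
         extrapolated_fraction = if (auc_inf > 0) {
           (auc_inf - auc_tlast) / auc_inf
         } else 0,
         ke_used = ke, clast_method = clast_method),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> Cmax = %.4g ug/mL at %.3g h; AUC(0-%.3g) = %.5g, ",
    x$cmax_obs, x$tmax_obs, x$tlast, x$auc_0_tlast))
  cat(sprintf("AUC(0-Inf) = %.5g h*ug/mL (%.1f%% extrapolated, clast %s)\n",
              x$auc_0_inf, 100 * x$extrapolated_fraction, x$clast_method))
  invisible(x)
}
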