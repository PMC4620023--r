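#' Cumulative in vitro release profile
#'
#' Container for a dissolution / Franz-cell release curve of one formulation:
#' sampling times in hours against cumulative percent of the dose released.
#'
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing, all `>= 0`.
#' @param released Numeric vector of cumulative percent released at each
#'   time. Values must lie in `[0, cap]`; the default cap of 110 tolerates a
#'   small assay overshoot above the nominal 100.
#' @param label Free-text formulation identifier.
#' @param cap Upper bound accepted for `released` (percent).
#'
#' @return An object of class `release_profile` with elements `times`,
#'   `released` and `label`.
#' @export
#' @examples
#' release_profile(1:6, 20 * sqrt(1:6), label = "higuchi-like")
release_profile <- function(times, released, label = "", cap = 110) {
  if (!is.numeric(times) || !is.numeric(released)) {
    stop("`times` and `released` must be numeric", call. = FALSE)
  }
  if (length(times) != length(released)) {
    stop("`times` and `released` must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("a release profile needs at least 3 points", call. = FALSE)
  }
  if (anyNA(times) || anyNA(released) || any(!is.finite(times)) ||
      any(!is.finite(released))) {
    stop("release profile values must be finite and non-missing", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(released < 0) || any(released > cap)) {
    stop(sprintf("released values must lie in [0, %g] percent", cap),
         call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), released = as.numeric(released),
         label = as.character(label)),
    class = "release_profile"
  )
}

#' @export
print.release_profile <- function(x, ...) {
  cat("<release_profile>", if (nzchar(x$label)) x$label else "(unlabelled)",
      "\n")
  cat(sprintf("  %d points over %.3g-%.3g h, release %.3g-%.3g%%\n",
              length(x$times), min(x$times), max(x$times),
              min(x$released), max(x$released)))
  invisible(x)
}
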