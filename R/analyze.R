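#' Build and validate an analysis run configuration
#'
#' Accepts a YAML or JSON file path, or an equivalent nested list, and
#' validates it before any computation. Two entry modes exist because raw
#' concentration profiles are often unpublished while summary tables are
#' printed:
#'
#' * `mode: "summary"` --- each arm supplies the published `ka`, `ke`,
#'   `cmax` and `auc_0_24` (plus optionally `dose`, default 1); the curve is
#'   reconstructed with [calibrate_from_summary()] and all downstream
#'   quantities are arithmetic on, or integrals of, that curve.
#' * `mode: "data"` --- each arm supplies a `conc_csv` path; the curve is
#'   fitted with [fit_bateman()] and NCA quantities come from the observed
#'   means.
#'
#' Shared keys: `mic90_ug_ml` (`> 0`), `threshold_multiplier` (default 2),
#' `horizon_h` (default 75), `n_terminal` (default 3), `grid_step_h`
#' (default 0.01), optional `release_csv`, optional `doses` per arm. The
#' `arms` list must contain `test` and `reference` entries.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("config must be .yaml, .yml or .json", call. = FALSE)
    )
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  defaults <- list(mode = "summary", threshold_multiplier = 2,
                   horizon_h = 75, n_terminal = 3, grid_step_h = 0.01,
                   release_csv = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("summary", "data")) {
    stop("mode must be \"summary\" or \"data\"", call. = FALSE)
  }
  if (is.null(cfg$mic90_ug_ml) || !is.numeric(cfg$mic90_ug_ml) ||
      cfg$mic90_ug_ml <= 0) {
    stop("mic90_ug_ml must be a positive number", call. = FALSE)
  }
  for (key in c("threshold_multiplier", "horizon_h", "grid_step_h")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop(key, " must be a positive number", call. = FALSE)
    }
  }
  if (is.null(cfg$arms) || !all(c("test", "reference") %in% names(cfg$arms))) {
    stop("config needs arms$test and arms$reference", call. = FALSE)
  }
  for (a in c("test", "reference")) {
    arm <- cfg$arms[[a]]
    if (cfg$mode == "summary") {
      need <- c("ka", "ke", "cmax", "auc_0_24")
      miss <- need[!vapply(need, function(k) {
        is.numeric(arm[[k]]) && arm[[k]] > 0
      }, logical(1))]
      if (length(miss)) {
        stop(sprintf("arm '%s': missing/invalid summary value(s): %s",
                     a, paste(miss, collapse = ", ")), call. = FALSE)
      }
    } else {
      if (is.null(arm$conc_csv) || !file.exists(arm$conc_csv)) {
        stop(sprintf("arm '%s': conc_csv missing or not found", a),
             call. = FALSE)
      }
    }
    if (!is.null(arm$dose) && (!is.numeric(arm$dose) || arm$dose <= 0)) {
      stop(sprintf("arm '%s': dose must be positive", a), call. = FALSE)
    }
  }
  if (!is.null(cfg$release_csv) && !file.exists(cfg$release_csv)) {
    stop("release_csv not found: ", cfg$release_csv, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.analyze_arm <- function(arm, name, cfg) {
  mic <- cfg$mic90_ug_ml
  k <- cfg$threshold_multiplier
  dose <- arm$dose %||% 1
  if (cfg$mode == "summary") {
    fit <- calibrate_from_summary(arm$ka, arm$ke, arm$cmax)
    tlast <- arm$tlast %||% 24
    clast_pred <- bateman_conc(fit, tlast)
    nca_res <- list(
      auc_0_tlast = arm$auc_0_24,
      auc_0_inf = extrapolate_auc_inf(arm$auc_0_24, clast_pred, arm$ke),
      clast = clast_pred, cmax_obs = arm$cmax,
      tmax_obs = fit$tmax, tlast = tlast,
      ke_used = arm$ke, clast_method = "predicted"
    )
    nca_res$extrapolated_fraction <-
      (nca_res$auc_0_inf - nca_res$auc_0_tlast) / nca_res$auc_0_inf
    class(nca_res) <- "nca_result"
    pkpd <- pkpd_report(fit, mic, k, cmax = arm$cmax,
                        auc_0_24 = arm$auc_0_24)
  } else {
    prof <- read_conc_csv(arm$conc_csv)
    if (is.list(prof) && !inherits(prof, "conc_profile")) {
      stop(sprintf("arm '%s': conc_csv holds multiple arms", name),
           call. = FALSE)
    }
    fit <- fit_bateman(prof, n_terminal = cfg$n_terminal)
    nca_res <- nca(prof, n_terminal = cfg$n_terminal)
    pkpd <- pkpd_report(fit, mic, k, cmax = nca_res$cmax_obs,
                        auc_0_24 = trapezoidal_auc(
                          prof, t_start = 0,
                          t_end = min(24, max(prof$times))))
  }
  tau <- pkpd$dosing_interval_tau
  sim <- if (is.finite(tau)) {
    superpose(fit, dosing_regimen(tau, cfg$horizon_h),
              grid_step = cfg$grid_step_h, mic = mic)
  } else {
    NULL
  }
  list(name = name, label = arm$label %||% name, dose = dose,
       fit = fit, nca = nca_res, pkpd = pkpd, simulation = sim)
}

#' Run the full single-report analysis chain
#'
#' Orchestrates, per treatment arm: curve reconstruction or fitting,
#' non-compartmental quantities, MIC-anchored PK/PD indices, the
#' threshold-based dosing interval and the superposition multi-dose
#' simulation; then the cross-arm comparison (relative bioavailability and
#' Cmax fold) and, when a release table is configured, the release-kinetics
#' ranking with mechanism classification. The result is a pure function of
#' the inputs: identical config and files give an identical report.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Object of class `analysis_report`: list with `arms` (each as
#'   returned arm bundle), `comparison`, `release` (or `NULL`) and the
#'   echoed `config`.
#' @export
analyze <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  arms <- list(
    test = .analyze_arm(cfg$arms$test, "test", cfg),
    reference = .analyze_arm(cfg$arms$reference, "reference", cfg)
  )
  comparison <- list(
    relative_bioavailability = relative_bioavailability(
      arms$test$nca$auc_0_tlast, arms$test$dose,
      arms$reference$nca$auc_0_tlast, arms$reference$dose),
    cmax_fold = arms$test$nca$cmax_obs / arms$reference$nca$cmax_obs,
    n_instillations = c(
      test = if (is.null(arms$test$simulation)) NA_integer_ else
        arms$test$simulation$n_instillations,
      reference = if (is.null(arms$reference$simulation)) NA_integer_ else
        arms$reference$simulation$n_instillations)
  )
  release <- NULL
  if (!is.null(cfg$release_csv)) {
    prof <- read_release_csv(cfg$release_csv)
    if (is.list(prof) && !inherits(prof, "release_profile")) {
      prof <- prof[[1]]
    }
    ranking <- select_release_models(prof)
    n_best <- attr(ranking, "fits")[["korsmeyer_peppas"]]
    release <- list(
      ranking = ranking,
      mechanism = if (!is.null(n_best) && is.finite(n_best$n_value)) {
        classify_mechanism(n_best$n_value)
      } else {
        NULL
      }
    )
  }
  structure(list(arms = arms, comparison = comparison, release = release,
                 config = cfg),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (a in x$arms) {
    cat(sprintf("-- arm '%s' (%s) --\n", a$name, a$label))
    print(a$fit)
    print(a$nca)
    print(a$pkpd)
    if (!is.null(a$simulation)) print(a$simulation)
  }
  cat(sprintf("relative bioavailability (test vs reference): %.4g\n",
              x$comparison$relative_bioavailability))
  cat(sprintf("Cmax fold: %.4g; instillations %s vs %s\n",
              x$comparison$cmax_fold,
              x$comparison$n_instillations["test"],
              x$comparison$n_instillations["reference"]))
  if (!is.null(x$release)) {
    cat("release-model ranking:\n")
    print(as.data.frame(x$release$ranking))
    if (!is.null(x$release$mechanism)) print(x$release$mechanism)
  }
  invisible(x)
}

.report_tables <- function(report) {
  arm_row <- function(a) {
    data.frame(
      arm = a$name, label = a$label,
      ka_per_h = a$fit$ka, ke_per_h = a$fit$ke, A_ug_ml = a$fit$A,
      tmax_h = a$fit$tmax, cmax_ug_ml = a$fit$cmax, t_half_h = a$fit$t_half,
      auc_0_tlast = a$nca$auc_0_tlast, auc_0_inf = a$nca$auc_0_inf,
      cmax_over_mic = a$pkpd$cmax_over_mic,
      auc24_over_mic = a$pkpd$auc24_over_mic,
      auc_above_mic = a$pkpd$auc_above_mic,
      t_above_mic_h = a$pkpd$t_above_mic,
      t_above_k_mic_h = a$pkpd$t_above_k_mic,
      dosing_interval_h = a$pkpd$dosing_interval_tau,
      n_instillations = if (is.null(a$simulation)) NA_integer_ else
        a$simulation$n_instillations,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(report$arms, arm_row))
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full precision) and `pkpd_indices.csv` (table
#' values rounded to 4 significant figures, the usual summary-table style)
#' plus, when present, `release_ranking.csv` and per-arm
#' `simulation_<arm>.csv` grids.
#'
#' @param report An [analyze()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- .report_tables(report)
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 4)
  utils::write.csv(out, file.path(dir, "pkpd_indices.csv"),
                   row.names = FALSE, quote = FALSE)
  payload <- list(
    arms = lapply(report$arms, function(a) {
      list(name = a$name, label = a$label, dose = a$dose,
           fit = a$fit[c("A", "ka", "ke", "tmax", "cmax", "t_half",
                         "flip_flop", "source")],
           nca = unclass(a$nca),
           pkpd = a$pkpd[c("mic90", "k", "cmax_over_mic", "auc24_over_mic",
                           "auc_above_mic", "t_above_mic", "t_above_k_mic",
                           "dosing_interval_tau", "provenance")],
           n_instillations = if (is.null(a$simulation)) NA else
             a$simulation$n_instillations,
           trough_concs = if (is.null(a$simulation)) NULL else
             a$simulation$trough_concs)
    }),
    comparison = report$comparison
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$release)) {
    utils::write.csv(as.data.frame(report$release$ranking),
                     file.path(dir, "release_ranking.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (a in report$arms) {
    if (!is.null(a$simulation)) {
      utils::write.csv(
        data.frame(time_h = a$simulation$grid_times,
                   total_conc = a$simulation$total_conc),
        file.path(dir, sprintf("simulation_%s.csv", a$name)),
        row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
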