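# CSV readers/writers for the two data dialects.
#
# Concentration tables: `time_h,conc_ug_ml[,replicate][,arm]`
# Release tables:       `time_h,released_pct[,label]`

.check_numeric_col <- function(df, col, path) {
  raw <- df[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !is.na(raw))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value in column '%s' at data row %d ('%s')",
                 path, col, bad[1], raw[bad[1]]), call. = FALSE)
  }
  nas <- which(is.na(vals))
  if (length(nas)) {
    stop(sprintf("%s: missing value in column '%s' at data row %d",
                 path, col, nas[1]), call. = FALSE)
  }
  vals
}

#' Read concentration-time CSV data
#'
#' Expects a header `time_h,conc_ug_ml` with optional `replicate` and `arm`
#' columns. Rows are validated (numeric cells, non-negative concentrations,
#' no duplicated `(time, replicate)` key within an arm) with row-numbered
#' error messages; out-of-order times are sorted with a warning.
#'
#' @param path CSV file path.
#' @return A single [conc_profile()] when the file holds one arm, otherwise
#'   a named list of profiles keyed by arm.
#' @export
read_conc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_ug_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  times <- .check_numeric_col(df, "time_h", path)
  conc <- .check_numeric_col(df, "conc_ug_ml", path)
  neg <- which(conc < 0)
  if (length(neg)) {
    stop(sprintf("%s: negative concentration at data row %d", path, neg[1]),
         call. = FALSE)
  }
  arm <- if ("arm" %in% names(df)) as.character(df$arm) else ""
  rep_col <- if ("replicate" %in% names(df)) as.character(df$replicate)
             else NULL
  key <- paste(arm, times, rep_col %||% seq_along(times))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("%s: duplicate (time, replicate) key at data row %d",
                 path, dup[1]), call. = FALSE)
  }
  build <- function(idx, label) {
    if (is.null(rep_col) && is.unsorted(times[idx], strictly = TRUE)) {
      warning(path, ": times out of order; sorting", call. = FALSE)
    }
    conc_profile(times[idx], conc[idx],
                 replicate = if (is.null(rep_col)) NULL else rep_col[idx],
                 arm = label)
  }
  arms <- unique(arm)
  if (length(arms) == 1L) {
    build(seq_along(times), arms)
  } else {
    stats::setNames(lapply(arms, function(a) build(which(arm == a), a)), arms)
  }
}

#' Read cumulative-release CSV data
#'
#' Expects a header `time_h,released_pct` with an optional `label` column
#' separating formulations.
#'
#' @param path CSV file path.
#' @return A single [release_profile()] or a named list keyed by label.
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "released_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  times <- .check_numeric_col(df, "time_h", path)
  rel <- .check_numeric_col(df, "released_pct", path)
  label <- if ("label" %in% names(df)) as.character(df$label) else ""
  labels <- unique(label)
  build <- function(idx, lab) {
    ord <- idx[order(times[idx])]
    if (!identical(ord, idx)) {
      warning(path, ": times out of order; sorting", call. = FALSE)
    }
    release_profile(times[ord], rel[ord], label = lab)
  }
  if (length(labels) == 1L) {
    build(seq_along(times), labels)
  } else {
    stats::setNames(lapply(labels, function(l) build(which(label == l), l)),
                    labels)
  }
}

#' Write a concentration profile as CSV
#'
#' Emits the same dialect [read_conc_csv()] consumes; replicate-level data
#' are written when present.
#'
#' @param profile A [conc_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conc_csv <- function(profile, path) {
  stopifnot(inherits(profile, "conc_profile"))
  df <- if (!is.null(profile$replicates)) {
    cbind(profile$replicates, arm = profile$arm)
  } else {
    data.frame(time_h = profile$times, conc_ug_ml = profile$concentrations,
               arm = profile$arm)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a release profile as CSV
#'
#' @param profile A [release_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  utils::write.csv(
    data.frame(time_h = profile$times, released_pct = profile$released,
               label = profile$label),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
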