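#' Egress event series and experiment datasets
#'
#' An `egress_series` holds one trial's ordered escape times, in seconds
#' relative to the first escape (the "time zero" convention: the instant the
#' first individual completely passes the exit). An `egress_dataset` is a
#' collection of such series, one per trial, spanning conditions
#' (repellent / control) and exit widths.
#'
#' @name egress-data
NULL

.conditions <- c("repellent", "control")

normalize_condition <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- !out %in% .conditions
  if (any(bad)) {
    stop("validation error: unknown condition label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected 'repellent' or 'control', case-insensitive)",
         call. = FALSE)
  }
  out
}

#' Construct a single-trial egress series
#'
#' Times may be absolute clock times in seconds; they are sorted and
#' re-referenced so the earliest escape is time zero.
#'
#' @param trial_id Opaque trial label.
#' @param condition `"repellent"` or `"control"` (case-insensitive).
#' @param exit_width_cm Exit width in cm, positive.
#' @param times_s Escape times in seconds (any reference point; re-referenced
#'   to the first escape). May be empty (a trial in which no ant escaped).
#' @param n_initial Number of ants placed in the chamber (default 30).
#' @return An object of class `egress_series`.
#' @export
egress_series <- function(trial_id, condition, exit_width_cm, times_s,
                          n_initial = 30L) {
  condition <- normalize_condition(condition)
  stopifnot(length(condition) == 1L, length(exit_width_cm) == 1L)
  exit_width_cm <- as.numeric(exit_width_cm)
  if (!is.finite(exit_width_cm) || exit_width_cm <= 0) {
    stop("validation error: exit_width_cm must be a positive number",
         call. = FALSE)
  }
  n_initial <- as.integer(n_initial)
  if (is.na(n_initial) || n_initial < 1L) {
    stop("validation error: n_initial must be a positive integer",
         call. = FALSE)
  }
  times_s <- as.numeric(times_s)
  if (anyNA(times_s)) {
    stop("validation error: times_s contains missing values", call. = FALSE)
  }
  if (length(times_s) > 0L) {
    times_s <- sort(times_s)
    times_s <- times_s - times_s[1L]
  }
  if (length(times_s) > n_initial) {
    stop("validation error: more escape events (", length(times_s),
         ") than agents placed (", n_initial, ") in trial '", trial_id, "'",
         call. = FALSE)
  }
  structure(
    list(
      trial_id = as.character(trial_id),
      condition = condition,
      exit_width_cm = exit_width_cm,
      n_initial = n_initial,
      times_s = times_s
    ),
    class = "egress_series"
  )
}

#' @export
print.egress_series <- function(x, ...) {
  cat(sprintf("<egress_series> trial '%s': %s, exit %.1f cm, %d/%d escaped",
              x$trial_id, x$condition, x$exit_width_cm,
              length(x$times_s), x$n_initial))
  if (length(x$times_s) > 1L) {
    cat(sprintf(", span %.2f s", max(x$times_s)))
  }
  cat("\n")
  invisible(x)
}

#' Construct an experiment dataset from egress series
#'
#' @param series List of [egress_series()] objects with unique trial ids.
#' @param provenance Free-text source note.
#' @return An object of class `egress_dataset`.
#' @export
egress_dataset <- function(series, provenance = "") {
  if (!is.list(series) ||
      !all(vapply(series, inherits, logical(1), "egress_series"))) {
    stop("series must be a list of egress_series objects", call. = FALSE)
  }
  ids <- vapply(series, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate trial_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(series) <- ids
  widths <- sort(unique(vapply(series, `[[`, numeric(1), "exit_width_cm")))
  structure(
    list(series = series, widths = widths,
         provenance = as.character(provenance)),
    class = "egress_dataset"
  )
}

#' @export
print.egress_dataset <- function(x, ...) {
  conds <- vapply(x$series, `[[`, character(1), "condition")
  cat(sprintf("<egress_dataset> %d trials (%d repellent, %d control), widths: %s cm\n",
              length(x$series), sum(conds == "repellent"),
              sum(conds == "control"),
              paste(format(x$widths), collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Flatten a dataset to the canonical event table
#'
#' One row per escape event, columns
#' `trial_id, condition, exit_width_cm, n_initial, egress_time_s`.
#' Trials with no events contribute no rows.
#'
#' @param dataset An [egress_dataset()].
#' @return A tibble.
#' @export
egress_events <- function(dataset) {
  stopifnot(inherits(dataset, "egress_dataset"))
  rows <- lapply(dataset$series, function(s) {
    k <- length(s$times_s)
    if (k == 0L) return(NULL)
    tibble::tibble(
      trial_id = rep(s$trial_id, k),
      condition = rep(s$condition, k),
      exit_width_cm = rep(s$exit_width_cm, k),
      n_initial = rep(s$n_initial, k),
      egress_time_s = s$times_s
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(
      trial_id = character(0), condition = character(0),
      exit_width_cm = numeric(0), n_initial = integer(0),
      egress_time_s = numeric(0)
    )
  }
  tibble::as_tibble(out)
}

#' Subset a dataset's series by condition and/or exit width
#'
#' @param dataset An [egress_dataset()].
#' @param condition Optional condition filter.
#' @param width Optional exit width filter (cm).
#' @return List of `egress_series`.
#' @export
dataset_series <- function(dataset, condition = NULL, width = NULL) {
  stopifnot(inherits(dataset, "egress_dataset"))
  keep <- dataset$series
  if (!is.null(condition)) {
    condition <- normalize_condition(condition)
    keep <- Filter(function(s) s$condition == condition, keep)
  }
  if (!is.null(width)) {
    keep <- Filter(function(s) isTRUE(all.equal(s$exit_width_cm, width)), keep)
  }
  keep
}
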