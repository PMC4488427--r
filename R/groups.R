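#' Group (burst) segmentation and the group flow rate Q_S
#'
#' Ants are regarded as a group when the interval between consecutive escapes
#' is strictly below the expectation threshold for that exit width (the
#' pooled mean interval). A group of N members spanning t_S = t_N - t_1
#' seconds has group flow rate Q_S = (N - 1) / t_S. A two-member group with
#' t_S = 0 (simultaneous escape on the video grid) makes Q_S infinite; such
#' groups are excluded from summaries and counted, mirroring the N >= 3
#' restriction used for the wider exits.
#'
#' @name group-flow
NULL

new_escape_group <- function(times_s) {
  S <- length(times_s)
  t1 <- times_s[1L]
  tN <- times_s[S]
  tS <- tN - t1
  structure(
    list(times_s = times_s, S = S, t1_s = t1, tN_s = tN, tS_s = tS,
         QS = if (S >= 2L && tS > 0) (S - 1) / tS else NA_real_),
    class = "escape_group"
  )
}

#' @export
print.escape_group <- function(x, ...) {
  cat(sprintf("<escape_group> S=%d span=%.3f s QS=%s\n", x$S, x$tS_s,
              if (is.na(x$QS)) "undefined" else sprintf("%.3f ants/s", x$QS)))
  invisible(x)
}

#' Segment a trial into escape groups
#'
#' Maximal runs of consecutive escapers whose consecutive intervals are
#' strictly below the threshold; an interval exactly equal to the threshold
#' splits groups. Singletons are retained in the result, so the groups
#' partition the trial's events in order.
#'
#' @param series An [egress_series()].
#' @param threshold_s Expectation threshold in seconds (> 0).
#' @return A `grouping_result` with `threshold_s`, `groups` (list of
#'   `escape_group`), `width_cm`, `trial_id`.
#' @export
segment_groups <- function(series, threshold_s) {
  stopifnot(inherits(series, "egress_series"))
  if (!is.numeric(threshold_s) || length(threshold_s) != 1L ||
      !is.finite(threshold_s) || threshold_s <= 0) {
    stop("domain error: threshold_s must be a positive number", call. = FALSE)
  }
  t <- series$times_s
  groups <- list()
  if (length(t)) {
    breaks <- which(diff(t) >= threshold_s)   # boundary after these indices
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(t))
    groups <- lapply(seq_along(starts), function(i) {
      new_escape_group(t[starts[i]:ends[i]])
    })
  }
  structure(
    list(threshold_s = threshold_s, groups = groups,
         width_cm = series$exit_width_cm, trial_id = series$trial_id),
    class = "grouping_result"
  )
}

#' @export
print.grouping_result <- function(x, ...) {
  sizes <- vapply(x$groups, `[[`, integer(1), "S")
  cat(sprintf("<grouping_result> trial '%s': %d groups (sizes %s), threshold %.3f s\n",
              x$trial_id, length(x$groups), paste(sizes, collapse = ","),
              x$threshold_s))
  invisible(x)
}

#' Group flow rate Q_S = (N - 1) / t_S
#'
#' @param group An `escape_group` with at least two members.
#' @return Q_S in ants per second.
#' @export
group_flow_rate <- function(group) {
  stopifnot(inherits(group, "escape_group"))
  if (group$S < 2L) {
    stop("domain error: group flow rate requires at least two members",
         call. = FALSE)
  }
  if (group$tS_s <= 0) {
    stop("singularity error: group evacuation time t_S is zero ",
         "(simultaneous escapes); Q_S is infinite", call. = FALSE)
  }
  (group$S - 1) / group$tS_s
}

#' Expectation thresholds per width
#'
#' The grouping threshold for each exit width is the pooled mean interval of
#' the repellent trials at that width, recomputed from the data under
#' analysis.
#'
#' @param dataset An [egress_dataset()].
#' @param condition Condition whose intervals define the expectation.
#' @return Named numeric vector, width key -> threshold (s).
#' @export
expectation_thresholds <- function(dataset, condition = "repellent") {
  stopifnot(inherits(dataset, "egress_dataset"))
  widths <- dataset$widths
  th <- vapply(widths, function(w) {
    mean_interval(pooled_intervals(dataset, w, condition))
  }, numeric(1))
  names(th) <- width_key(widths)
  th
}

default_min_size <- function(width) if (abs(width - 0.5) < 1e-9) 2L else 3L

#' Collect group statistics across a dataset
#'
#' Segments every repellent trial with its width's threshold and returns one
#' row per qualifying group (size at least `min_size` and a defined Q_S).
#' Groups of two or more that span zero time (the t_S = 0 singularity) are
#' excluded and counted in the `n_singular` attribute.
#'
#' @param dataset An [egress_dataset()].
#' @param thresholds Named numeric vector width key -> threshold (s); default
#'   [expectation_thresholds()] of the dataset.
#' @param min_size Minimum group size, an integer >= 2 applied to all widths,
#'   or `NULL` for the width policy: 2 for the 0.5 cm exit, 3 otherwise.
#' @param condition Condition to segment (default repellent).
#' @return A tibble with columns `width_cm, trial_id, group_index, S, t1_s,
#'   tN_s, tS_s, QS`, and attribute `n_singular`.
#' @export
collect_group_stats <- function(dataset, thresholds = NULL, min_size = NULL,
                                condition = "repellent") {
  stopifnot(inherits(dataset, "egress_dataset"))
  if (is.null(thresholds)) {
    thresholds <- expectation_thresholds(dataset, condition)
  }
  if (!is.null(min_size) && min_size < 2L) {
    stop("domain error: min_size must be at least 2", call. = FALSE)
  }
  series <- dataset_series(dataset, condition = condition)
  rows <- list()
  n_singular <- 0L
  for (s in series) {
    key <- width_key(s$exit_width_cm)
    if (!key %in% names(thresholds)) {
      stop("configuration error: no threshold defined for width ", key,
           " cm", call. = FALSE)
    }
    msize <- if (is.null(min_size)) default_min_size(s$exit_width_cm)
             else as.integer(min_size)
    gr <- segment_groups(s, thresholds[[key]])
    for (i in seq_along(gr$groups)) {
      g <- gr$groups[[i]]
      if (g$S < msize) next
      if (g$tS_s <= 0) {
        n_singular <- n_singular + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        width_cm = s$exit_width_cm, trial_id = s$trial_id,
        group_index = i, S = g$S, t1_s = g$t1_s, tN_s = g$tN_s,
        tS_s = g$tS_s, QS = g$QS
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    width_cm = numeric(0), trial_id = character(0), group_index = integer(0),
    S = integer(0), t1_s = numeric(0), tN_s = numeric(0), tS_s = numeric(0),
    QS = numeric(0)
  )
  out <- tibble::as_tibble(out)
  attr(out, "n_singular") <- n_singular
  out
}

#' Mean group flow rate for one width
#'
#' @param rows A group-statistics tibble (one width) as produced by
#'   [collect_group_stats()].
#' @param min_size Minimum group size to include (default 3, the restriction
#'   used for exits wider than 0.5 cm).
#' @return Mean Q_S (ants/s) over qualifying groups.
#' @export
mean_group_flow_rate <- function(rows, min_size = 3L) {
  qs <- rows$QS[rows$S >= min_size & is.finite(rows$QS)]
  if (!length(qs)) {
    stop("domain error: no qualifying groups (S >= ", min_size,
         ") with a defined Q_S", call. = FALSE)
  }
  mean(qs)
}
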