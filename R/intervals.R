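#' Inter-escape intervals and their summaries
#'
#' The time interval (headway) is the elapsed time between two consecutive
#' escapes in one trial, measured from the first ant to the last. A series of
#' k events yields k - 1 intervals; ties on the video grid yield zero
#' intervals.
#'
#' @name intervals
NULL

new_interval_set <- function(intervals_s, exit_width_cm, condition, source) {
  structure(
    list(
      exit_width_cm = exit_width_cm,
      condition = condition,
      intervals_s = as.numeric(intervals_s),
      source = source
    ),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d intervals, exit %.1f cm, %s (%s)\n",
              length(x$intervals_s), x$exit_width_cm, x$condition, x$source))
  invisible(x)
}

#' Compute inter-escape intervals for one trial
#'
#' @param series An [egress_series()].
#' @return An `interval_set` with the successive differences of the escape
#'   times (empty when the trial has fewer than two events).
#' @export
compute_intervals <- function(series) {
  stopifnot(inherits(series, "egress_series"))
  new_interval_set(diff(series$times_s), series$exit_width_cm,
                   series$condition, source = "per_trial")
}

#' Pool interval sets across repetitions of one width
#'
#' @param sets List of `interval_set` objects sharing width and condition.
#' @param width Expected exit width (cm); defaults to the first set's width.
#' @return A pooled `interval_set`.
#' @export
pool_intervals <- function(sets, width = NULL) {
  if (inherits(sets, "interval_set")) sets <- list(sets)
  stopifnot(length(sets) > 0L,
            all(vapply(sets, inherits, logical(1), "interval_set")))
  widths <- vapply(sets, `[[`, numeric(1), "exit_width_cm")
  if (is.null(width)) width <- widths[1L]
  if (any(abs(widths - width) > 1e-9)) {
    stop("validation error: cannot pool interval sets with mixed exit widths (",
         paste(format(sort(unique(widths))), collapse = ", "), ")",
         call. = FALSE)
  }
  conds <- unique(vapply(sets, `[[`, character(1), "condition"))
  if (length(conds) > 1L) {
    stop("validation error: cannot pool interval sets with mixed conditions",
         call. = FALSE)
  }
  new_interval_set(unlist(lapply(sets, `[[`, "intervals_s")),
                   width, conds, source = "pooled")
}

#' Pooled intervals for one width and condition of a dataset
#'
#' @param dataset An [egress_dataset()].
#' @param width Exit width (cm).
#' @param condition Condition (default repellent).
#' @return A pooled `interval_set`.
#' @export
pooled_intervals <- function(dataset, width, condition = "repellent") {
  series <- dataset_series(dataset, condition = condition, width = width)
  if (!length(series)) {
    stop("validation error: no ", condition, " trials at width ", width,
         " cm", call. = FALSE)
  }
  pool_intervals(lapply(series, compute_intervals), width = width)
}

#' Mean inter-escape interval (the "mathematical expectation")
#'
#' @param set An `interval_set`.
#' @return Mean interval in seconds.
#' @export
mean_interval <- function(set) {
  stopifnot(inherits(set, "interval_set"))
  if (!length(set$intervals_s)) {
    stop("domain error: mean interval undefined for an empty interval set",
         call. = FALSE)
  }
  mean(set$intervals_s)
}

#' Mean flow rate Q
#'
#' The mean time interval is the inverse of the mean flow rate:
#' Q = 1 / mean interval, in ants per second.
#'
#' @param set An `interval_set`.
#' @return Q in ants/s.
#' @export
mean_flow_rate <- function(set) {
  m <- mean_interval(set)
  if (m <= 0) {
    stop("domain error: mean interval is zero (all escapes simultaneous); ",
         "flow rate undefined", call. = FALSE)
  }
  1 / m
}

#' Histogram of inter-escape intervals
#'
#' Bins span `[0, max(interval)]` with equal widths. The default Sturges rule
#' uses `k = ceiling(1 + log2(n))` bins; Scott's rule uses the normal
#' reference bandwidth; `fixed_width` uses a caller-supplied bin width. Bins
#' are left-closed, the last bin right-closed, so the counts partition the
#' data.
#'
#' @param set An `interval_set` (non-empty).
#' @param rule `"sturges"`, `"scott"`, or `"fixed_width"`.
#' @param fixed_width_s Bin width in seconds, required for `"fixed_width"`.
#' @return An `interval_histogram` with `bin_edges_s`, `counts`, `rule`,
#'   `n_total` and the set's width/condition.
#' @export
build_histogram <- function(set, rule = c("sturges", "scott", "fixed_width"),
                            fixed_width_s = NULL) {
  stopifnot(inherits(set, "interval_set"))
  rule <- match.arg(rule)
  x <- set$intervals_s
  n <- length(x)
  if (!n) {
    stop("domain error: cannot bin an empty interval set", call. = FALSE)
  }
  xmax <- max(x)
  if (rule == "fixed_width" && is.null(fixed_width_s)) {
    stop("configuration error: fixed_width rule requires fixed_width_s",
         call. = FALSE)
  }
  if (xmax <= 0) {
    # all escapes simultaneous: a single degenerate bin holds everything
    edges <- c(0, if (rule == "fixed_width") fixed_width_s else 1)
  } else {
    k <- switch(rule,
      sturges = ceiling(1 + log2(n)),
      scott = {
        s <- stats::sd(x)
        h <- 3.49 * s * n^(-1 / 3)
        if (!is.finite(h) || h <= 0) 1L else max(1L, ceiling(xmax / h))
      },
      fixed_width = max(1L, ceiling(xmax / fixed_width_s))
    )
    edges <- seq(0, xmax, length.out = k + 1L)
    if (rule == "fixed_width") edges <- seq(0, k * fixed_width_s,
                                            by = fixed_width_s)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(
      bin_edges_s = edges,
      counts = counts,
      rule = rule,
      n_total = n,
      exit_width_cm = set$exit_width_cm,
      condition = set$condition
    ),
    class = "interval_histogram"
  )
}

#' Bin midpoints of an interval histogram
#' @param hist An `interval_histogram`.
#' @return Numeric vector of midpoints (seconds).
#' @export
histogram_midpoints <- function(hist) {
  stopifnot(inherits(hist, "interval_histogram"))
  e <- hist$bin_edges_s
  (e[-length(e)] + e[-1L]) / 2
}
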