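#' Comparative statistics with star annotation
#'
#' Two-sample t tests (Welch by default) with the conventional star coding:
#' one, two and three stars for two-tailed p strictly below 0.05, 0.01 and
#' 0.001 respectively; no multiple-testing correction by default.
#'
#' @name comparison-stats
NULL

#' Star annotation for a p-value
#'
#' Strict thresholds: 3 stars if p < 0.001, 2 if p < 0.01, 1 if p < 0.05,
#' else 0. Exactly 0.05 earns no star.
#'
#' @param p Two-tailed p-value(s).
#' @return Integer star count(s) 0-3.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_integer_)
    if (pi < 0.001) 3L else if (pi < 0.01) 2L else if (pi < 0.05) 1L else 0L
  }, integer(1))
}

new_comparison_result <- function(statistic, p, labels, n_a, n_b) {
  structure(
    list(statistic = statistic, p_two_tailed = p, stars = p_stars(p),
         group_labels = labels, n_a = n_a, n_b = n_b),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: t=%.4g, p=%.4g %s (n=%d,%d)\n",
              x$group_labels[1L], x$group_labels[2L], x$statistic,
              x$p_two_tailed, strrep("*", x$stars), x$n_a, x$n_b))
  invisible(x)
}

#' Two-sample t test with stars
#'
#' Welch's unequal-variance test by default; a pooled-variance variant is
#' available. Requires at least two values per sample and a nonzero combined
#' variance (one sample may be constant; both constant is degenerate).
#'
#' @param a,b Numeric samples.
#' @param variant `"welch"` or `"pooled"`.
#' @param labels Length-2 character labels for the two samples.
#' @return A `comparison_result` with `statistic`, `p_two_tailed`, `stars`.
#' @export
two_sample_t_test <- function(a, b, variant = c("welch", "pooled"),
                              labels = c("a", "b")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("domain error: each sample needs at least 2 values (got ",
         length(a), " and ", length(b), ")", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (a[1L] == b[1L]) {
      # identical constants: no evidence of any difference
      return(new_comparison_result(0, 1, labels, length(a), length(b)))
    }
    stop("domain error: both samples are constant; t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  new_comparison_result(unname(ht$statistic), unname(ht$p.value),
                        labels, length(a), length(b))
}

#' Pairwise interval comparisons across exit widths
#'
#' Pools the intervals of all repetitions per width and runs a two-sample t
#' test for every unordered pair of widths (15 pairs for 6 widths). P-values
#' are uncorrected by default, matching the original analysis; `adjust` can
#' apply [stats::p.adjust()] methods, with stars then derived from the
#' adjusted values.
#'
#' @param dataset An [egress_dataset()].
#' @param condition Condition to compare (default repellent).
#' @param variant t-test variant, see [two_sample_t_test()].
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return A tibble with one row per pair (`width_a`, `width_b`, `statistic`,
#'   `p`, `stars`, `n_a`, `n_b`), plus symmetric matrices of p-values and
#'   stars in attributes `p_matrix` and `stars_matrix`.
#' @export
pairwise_interval_tests <- function(dataset, condition = "repellent",
                                    variant = "welch", adjust = "none") {
  stopifnot(inherits(dataset, "egress_dataset"))
  widths <- dataset$widths
  has_cond <- vapply(widths, function(w) {
    length(dataset_series(dataset, condition = condition, width = w)) > 0
  }, logical(1))
  widths <- widths[has_cond]
  if (length(widths) < 2L) {
    stop("validation error: need interval samples for at least 2 widths",
         call. = FALSE)
  }
  samples <- lapply(widths, function(w) {
    pooled_intervals(dataset, w, condition)$intervals_s
  })
  names(samples) <- width_key(widths)
  pairs <- utils::combn(seq_along(widths), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    r <- two_sample_t_test(samples[[i1]], samples[[i2]], variant = variant,
                           labels = width_key(widths[c(i1, i2)]))
    tibble::tibble(width_a = widths[i1], width_b = widths[i2],
                   statistic = r$statistic, p = r$p_two_tailed,
                   n_a = r$n_a, n_b = r$n_b)
  })
  out <- tibble::as_tibble(do.call(rbind, res))
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out$stars <- p_stars(out$p_adjusted)
  k <- length(widths)
  pm <- matrix(NA_real_, k, k, dimnames = list(width_key(widths),
                                               width_key(widths)))
  sm <- matrix(NA_integer_, k, k, dimnames = dimnames(pm))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    pm[i1, i2] <- pm[i2, i1] <- out$p_adjusted[j]
    sm[i1, i2] <- sm[i2, i1] <- out$stars[j]
  }
  attr(out, "p_matrix") <- pm
  attr(out, "stars_matrix") <- sm
  out
}

#' Pearson correlation between group size S and group flow rate Q_S
#'
#' Product-moment correlation with a two-tailed p-value from the t transform
#' on n - 2 degrees of freedom.
#'
#' @param s_values Group sizes.
#' @param qs_values Group flow rates.
#' @return A `correlation_result` with `r`, `p_two_tailed`, `n`.
#' @export
pearson_correlation <- function(s_values, qs_values) {
  s <- as.numeric(s_values); q <- as.numeric(qs_values)
  n <- length(s)
  if (n != length(q)) {
    stop("domain error: inputs differ in length", call. = FALSE)
  }
  if (n < 3L) {
    stop("domain error: correlation needs at least 3 pairs", call. = FALSE)
  }
  if (stats::var(s) == 0 || stats::var(q) == 0) {
    stop("domain error: correlation undefined for a constant input",
         call. = FALSE)
  }
  r <- stats::cor(s, q)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, p_two_tailed = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r=%.3f, p=%.4g (n=%d)\n",
              x$r, x$p_two_tailed, x$n))
  invisible(x)
}

#' Treatment-vs-control comparison of escaped counts at one width
#'
#' Per-trial escaped counts (repellent vs control) compared by a two-sample
#' t test; in the original design 6 repellent and 3 control repetitions.
#'
#' @param dataset An [egress_dataset()].
#' @param width Exit width (cm).
#' @param variant t-test variant, see [two_sample_t_test()].
#' @return A `comparison_result`.
#' @export
treatment_vs_control_counts <- function(dataset, width, variant = "welch") {
  stopifnot(inherits(dataset, "egress_dataset"))
  rep_counts <- vapply(dataset_series(dataset, "repellent", width),
                       function(s) length(s$times_s), integer(1))
  ctl_counts <- vapply(dataset_series(dataset, "control", width),
                       function(s) length(s$times_s), integer(1))
  if (length(rep_counts) < 2L || length(ctl_counts) < 2L) {
    stop("domain error: need at least 2 repellent and 2 control trials at ",
         "width ", width, " cm (got ", length(rep_counts), " and ",
         length(ctl_counts), ")", call. = FALSE)
  }
  two_sample_t_test(rep_counts, ctl_counts, variant = variant,
                    labels = c("repellent", "control"))
}
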