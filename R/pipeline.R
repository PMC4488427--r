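#' Run the full egress analysis
#'
#' Executes every stage in order on one dataset: inter-escape intervals per
#' width, histograms, exponential-decay fits, mean intervals and mean flow
#' rate Q, the beta-vs-width trend, expectation-threshold group segmentation
#' with Q_S summaries, S-Q_S Pearson correlations, pairwise interval t tests,
#' and (when control trials are present) treatment-vs-control escaped-count
#' tests. Deterministic given the dataset and options; a non-converged fit is
#' recorded in its `converged` flag, not raised.
#'
#' @param dataset An [egress_dataset()] with at least one repellent series.
#' @param options A list of options: `bins` (histogram rule, default
#'   `"sturges"`), `fixed_width_s`, `thresholds` (named width -> seconds
#'   override of the data-derived expectations), `min_size` (`NULL` for the
#'   width policy: 2 at 0.5 cm, 3 otherwise), `variant` (t-test variant),
#'   `adjust` (p-value correction, default `"none"`).
#' @return An `egress_report` list with elements `per_width`, `beta_trend`,
#'   `groups`, `group_summary`, `correlations`, `pairwise_tests`,
#'   `control_tests`, `provenance`.
#' @export
run_analysis <- function(dataset, options = list()) {
  stopifnot(inherits(dataset, "egress_dataset"))
  opt <- utils::modifyList(
    list(bins = "sturges", fixed_width_s = NULL, thresholds = NULL,
         min_size = NULL, variant = "welch", adjust = "none"),
    options
  )
  rep_series <- dataset_series(dataset, condition = "repellent")
  if (!length(rep_series)) {
    stop("input error: dataset has no repellent series", call. = FALSE)
  }
  widths <- sort(unique(vapply(rep_series, `[[`, numeric(1),
                               "exit_width_cm")))

  per_width <- do.call(rbind, lapply(widths, function(w) {
    iv <- pooled_intervals(dataset, w, "repellent")
    m <- mean_interval(iv)
    hist <- build_histogram(iv, rule = opt$bins,
                            fixed_width_s = opt$fixed_width_s)
    fit <- if (length(hist$counts) >= 3L) fit_interval_frequency(hist)
           else new_exp_decay_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                                  FALSE, n_bins = length(hist$counts))
    tibble::tibble(
      width_cm = w, n_intervals = length(iv$intervals_s),
      mean_interval_s = m, Q = 1 / m,
      alpha = fit$alpha, beta = fit$beta, epsilon = fit$epsilon,
      sse = fit$sse, converged = fit$converged
    )
  }))
  per_width <- tibble::as_tibble(per_width)

  trend <- if (sum(per_width$converged) >= 2L) {
    ok <- per_width$converged
    beta_trend(data.frame(width_cm = per_width$width_cm[ok],
                          beta_s = per_width$beta[ok]))
  } else NULL

  thresholds <- opt$thresholds
  if (is.null(thresholds)) {
    thresholds <- expectation_thresholds(dataset, "repellent")
  }
  groups <- collect_group_stats(dataset, thresholds = thresholds,
                                min_size = opt$min_size)
  group_summary <- do.call(rbind, lapply(widths, function(w) {
    rows <- groups[abs(groups$width_cm - w) < 1e-9, ]
    msize <- if (is.null(opt$min_size)) default_min_size(w)
             else as.integer(opt$min_size)
    mqs <- tryCatch(mean_group_flow_rate(rows, min_size = msize),
                    error = function(e) NA_real_)
    tibble::tibble(width_cm = w, n_groups = nrow(rows), min_size = msize,
                   mean_QS = mqs,
                   Q = per_width$Q[match(w, per_width$width_cm)])
  }))
  group_summary <- tibble::as_tibble(group_summary)

  correlations <- lapply(widths, function(w) {
    rows <- groups[abs(groups$width_cm - w) < 1e-9, ]
    res <- tryCatch(pearson_correlation(rows$S, rows$QS),
                    error = function(e) NULL)
    if (is.null(res)) NULL else
      list(width_cm = w, r = res$r, p_two_tailed = res$p_two_tailed,
           n = res$n)
  })
  correlations <- Filter(Negate(is.null), correlations)

  pairwise <- if (length(widths) >= 2L) {
    pairwise_interval_tests(dataset, condition = "repellent",
                            variant = opt$variant, adjust = opt$adjust)
  } else NULL

  control_tests <- lapply(widths, function(w) {
    res <- tryCatch(
      treatment_vs_control_counts(dataset, w, variant = opt$variant),
      error = function(e) NULL)
    if (is.null(res)) NULL else
      list(width_cm = w, statistic = res$statistic,
           p_two_tailed = res$p_two_tailed, stars = res$stars,
           n_repellent = res$n_a, n_control = res$n_b)
  })
  control_tests <- Filter(Negate(is.null), control_tests)

  structure(
    list(
      per_width = per_width,
      beta_trend = if (is.null(trend)) NULL else unclass(trend),
      groups = groups,
      group_summary = group_summary,
      n_singular_groups = attr(groups, "n_singular"),
      correlations = correlations,
      pairwise_tests = pairwise,
      control_tests = control_tests,
      provenance = list(
        source = dataset$provenance,
        n_trials = length(dataset$series),
        options = opt[c("bins", "variant", "adjust")],
        thresholds_s = as.list(thresholds),
        schema_version = "1.0",
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "egress_report"
  )
}

#' @export
print.egress_report <- function(x, ...) {
  cat("<egress_report>\n")
  cat("Per-width interval summaries:\n")
  print(x$per_width)
  if (!is.null(x$beta_trend)) {
    cat(sprintf("beta trend: slope %.3f s/cm, intercept %.3f s, r^2 %.3f\n",
                x$beta_trend$slope, x$beta_trend$intercept,
                x$beta_trend$r_squared))
  }
  cat("Group flow-rate summary:\n")
  print(x$group_summary)
  cat(sprintf("Singular (t_S = 0) groups excluded: %d\n",
              x$n_singular_groups))
  invisible(x)
}

report_to_list <- function(report, drop_timestamp = FALSE) {
  out <- unclass(report)
  out$per_width <- as.data.frame(out$per_width)
  out$groups <- as.data.frame(out$groups)
  attr(out$groups, "n_singular") <- NULL
  out$group_summary <- as.data.frame(out$group_summary)
  if (!is.null(out$pairwise_tests)) {
    pt <- as.data.frame(out$pairwise_tests)
    attr(pt, "p_matrix") <- NULL
    attr(pt, "stars_matrix") <- NULL
    out$pairwise_tests <- pt
  }
  if (drop_timestamp) out$provenance$timestamp <- NULL
  out
}

#' Write an analysis report to JSON
#'
#' The JSON layout is described by the schema shipped at
#' `system.file("schema", "report-schema.json", package = "egressr")`.
#' Identical inputs and options give byte-identical output except for the
#' provenance timestamp.
#'
#' @param report An `egress_report` from [run_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "egress_report"))
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Write the tidy per-width and group tables of a report to CSV
#'
#' @param report An `egress_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "egress_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    per_width = file.path(dir, "per_width_summary.csv"),
    groups = file.path(dir, "groups.csv"),
    group_summary = file.path(dir, "group_summary.csv")
  )
  readr::write_csv(report$per_width, paths[["per_width"]], progress = FALSE)
  readr::write_csv(report$groups, paths[["groups"]], progress = FALSE)
  readr::write_csv(report$group_summary, paths[["group_summary"]],
                   progress = FALSE)
  if (!is.null(report$pairwise_tests)) {
    paths <- c(paths, pairwise = file.path(dir, "pairwise_tests.csv"))
    readr::write_csv(report$pairwise_tests, paths[["pairwise"]],
                     progress = FALSE)
  }
  invisible(paths)
}
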