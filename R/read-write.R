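#' Read an egress event table
#'
#' Reads a delimited event table (or an XLSX sheet) into an
#' [egress_dataset()]. Required columns: `trial_id`, `condition`,
#' `exit_width_cm`, `egress_time_s`; `n_initial` is optional and defaults to
#' 30. Times may be absolute; each trial is re-referenced so its first escape
#' is time zero. Row order in the file is irrelevant.
#'
#' For XLSX input the sheet layout is not guessed: a `col_map` naming the
#' source column for each canonical column must be supplied.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"`, `"tsv"`, or `"xlsx"`.
#' @param col_map Named character vector mapping canonical column names to
#'   source column names, e.g. `c(trial_id = "Trial", ...)`. Required for
#'   xlsx; optional renaming for csv/tsv.
#' @param sheet Sheet index or name for xlsx (default first sheet).
#' @param n_initial_default Used when the table has no `n_initial` column.
#' @return An [egress_dataset()].
#' @export
read_egress_table <- function(path, dialect = c("auto", "csv", "tsv", "xlsx"),
                              col_map = NULL, sheet = 1L,
                              n_initial_default = 30L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", txt = "tsv", xlsx = "xlsx", "csv")
  }
  raw <- switch(dialect,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    xlsx = {
      if (is.null(col_map)) {
        stop("configuration error: xlsx import requires an explicit col_map ",
             "(the sheet layout is not guessed)", call. = FALSE)
      }
      readxl::read_excel(path, sheet = sheet,
                         col_types = "text", .name_repair = "minimal")
    }
  )
  raw <- tibble::as_tibble(raw, .name_repair = "minimal")
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(unlist(col_map)), names(raw))
    if (length(missing_src)) {
      stop("format error: mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(col_map)) {
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  required <- c("trial_id", "condition", "exit_width_cm", "egress_time_s")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad)) {
      stop("parse error: non-numeric ", col, " at data row ", bad[1L],
           " (value '", x[bad[1L]], "')", call. = FALSE)
    }
    if (anyNA(out)) {
      stop("parse error: missing ", col, " at data row ",
           which(is.na(out))[1L], call. = FALSE)
    }
    out
  }
  times <- parse_num(raw$egress_time_s, "egress_time_s")
  widths <- parse_num(raw$exit_width_cm, "exit_width_cm")
  conds <- normalize_condition(raw$condition)
  n_init <- if ("n_initial" %in% names(raw)) {
    as.integer(parse_num(raw$n_initial, "n_initial"))
  } else {
    rep(as.integer(n_initial_default), nrow(raw))
  }
  ids <- as.character(raw$trial_id)

  series <- lapply(split(seq_len(nrow(raw)), factor(ids, levels = unique(ids))),
                   function(i) {
    if (length(unique(conds[i])) > 1L ||
        length(unique(widths[i])) > 1L || length(unique(n_init[i])) > 1L) {
      stop("validation error: trial '", ids[i[1L]],
           "' has inconsistent condition/width/n_initial across rows",
           call. = FALSE)
    }
    egress_series(ids[i[1L]], conds[i[1L]], widths[i[1L]],
                  times[i], n_init[i[1L]])
  })
  egress_dataset(unname(series), provenance = path)
}

#' Write an egress dataset to the canonical CSV event table
#'
#' Header exactly `trial_id,condition,exit_width_cm,n_initial,egress_time_s`;
#' one row per escape event; UTF-8 with '.' decimal separator. An empty
#' dataset yields a header-only file.
#'
#' @param dataset An [egress_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_egress_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "egress_dataset"))
  readr::write_csv(egress_events(dataset), path, progress = FALSE)
  invisible(path)
}
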