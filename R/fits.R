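#' Nonlinear fits: interval-frequency decay, escape curve, beta trend
#'
#' The interval-frequency model is
#'   p_f(dt) = alpha * exp(-dt / beta) + epsilon,
#' fitted by unweighted least squares to (bin midpoint, relative frequency)
#' pairs of an interval histogram; one (alpha, beta, epsilon) triple per exit
#' width. beta (seconds) is the decay scale: larger beta means a heavier
#' long-interval tail. The cumulative escape curve is
#'   y(x) = A1 * exp(-x / t1) + y0,
#' with y the number escaped by time x; for a rising saturating count A1 < 0
#' and y0 approximates the final escaped count.
#'
#' @name decay-fits
NULL

new_exp_decay_fit <- function(alpha, beta, epsilon, sse, converged,
                              n_bins = NA_integer_) {
  structure(
    list(alpha = alpha, beta = beta, epsilon = epsilon,
         sse = sse, converged = converged, n_bins = n_bins),
    class = "exp_decay_fit"
  )
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit> alpha=%.4g beta=%.4g s epsilon=%.4g sse=%.3g%s\n",
    x$alpha, x$beta, x$epsilon, x$sse,
    if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Fit the exponential-decay interval-frequency model
#'
#' Least-squares fit of `alpha * exp(-t / beta) + epsilon` to relative
#' frequencies (`count / n_total`) at bin midpoints. Starting values are
#' moment-based: epsilon0 = min frequency, alpha0 = max - min frequency,
#' beta0 = count-weighted mean midpoint (the binned mean interval).
#' Non-convergence is reported in the `converged` flag, never as an error.
#'
#' @param hist An `interval_histogram` with at least 3 bins.
#' @return An `exp_decay_fit` with fields `alpha`, `beta` (s), `epsilon`,
#'   `sse`, `converged`.
#' @export
fit_interval_frequency <- function(hist) {
  stopifnot(inherits(hist, "interval_histogram"))
  mids <- histogram_midpoints(hist)
  if (length(mids) < 3L) {
    stop("domain error: need at least 3 bins to fit the decay model (got ",
         length(mids), ")", call. = FALSE)
  }
  freq <- hist$counts / hist$n_total
  eps0 <- min(freq)
  alpha0 <- max(freq) - eps0
  if (alpha0 <= 0) alpha0 <- max(max(freq), 1e-6)
  # moment start: count-weighted mean midpoint, the binned mean interval
  beta_m <- sum(mids * hist$counts) / sum(hist$counts)
  if (!is.finite(beta_m) || beta_m <= 0) beta_m <- mean(mids)
  starts <- list(list(a = alpha0, b = beta_m, e = eps0))
  # log-linear start: regress log(freq - eps) on midpoints where positive
  pos <- which(freq - eps0 > 0)
  if (length(pos) >= 2L) {
    ll <- stats::lm(log(freq[pos] - eps0) ~ mids[pos])
    sl <- unname(stats::coef(ll)[2L])
    if (is.finite(sl) && sl < 0) {
      starts <- c(starts, list(list(
        a = max(exp(unname(stats::coef(ll)[1L])), 1e-9),
        b = -1 / sl, e = eps0)))
    }
  }
  # coarse fallback start on the histogram span
  starts <- c(starts, list(list(a = alpha0, b = max(mids) / 3, e = eps0)))

  df <- data.frame(t = mids, f = freq)
  sse_of <- function(par) {
    if (par[1L] < 0 || par[2L] <= 0) return(Inf)
    sum((freq - (par[1L] * exp(-mids / par[2L]) + par[3L]))^2)
  }
  best <- NULL
  keep_best <- function(a, b, e, sse, converged) {
    if (is.null(best) || sse < best$sse ||
        (isTRUE(converged) && !best$converged && sse <= best$sse)) {
      best <<- list(a = a, b = b, e = e, sse = sse, converged = converged)
    }
  }
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(f ~ a * exp(-t / b) + e, data = df, start = st,
                 lower = c(a = 0, b = 1e-9, e = -Inf),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      keep_best(unname(cf["a"]), unname(cf["b"]), unname(cf["e"]),
                sum(stats::resid(fit)^2), TRUE)
    }
    # derivative-free polish; rescues near-flat SSE surfaces where the
    # Gauss-Newton iteration reports false convergence
    par <- unlist(st)
    for (round in 1:2) {
      om <- tryCatch(
        stats::optim(par, sse_of, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(om)) break
      par <- om$par
      keep_best(om$par[1L], om$par[2L], om$par[3L], om$value,
                om$convergence == 0L)
    }
  }
  if (is.null(best)) {
    sse0 <- sum((freq - (alpha0 * exp(-mids / beta_m) + eps0))^2)
    return(new_exp_decay_fit(alpha0, beta_m, eps0, sse0, FALSE,
                             n_bins = length(mids)))
  }
  new_exp_decay_fit(best$a, best$b, best$e, best$sse, best$converged,
                    n_bins = length(mids))
}

#' Fit the cumulative escape curve
#'
#' The cumulative escaped count is a right-continuous step function sampled
#' at the event times (at the i-th escape time the count is i); the model
#' `y = A1 * exp(-x / t1) + y0` is fitted by least squares.
#'
#' @param series An [egress_series()] with at least 4 events.
#' @return An `escape_curve_fit` with `y0`, `A1`, `t1` (s), `sse`,
#'   `converged`.
#' @export
fit_escape_curve <- function(series) {
  stopifnot(inherits(series, "egress_series"))
  x <- series$times_s
  if (length(x) < 4L) {
    stop("domain error: need at least 4 escape events to fit the escape ",
         "curve (got ", length(x), ")", call. = FALSE)
  }
  y <- seq_along(x)
  n <- length(x)
  y0_0 <- n
  A1_0 <- 1 - n          # y(0) = 1 escaped at time zero
  t1_0 <- max(max(x) / 3, 1e-3)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    stats::nls(y ~ A1 * exp(-x / t1) + y0, data = df,
               start = list(A1 = A1_0, t1 = t1_0, y0 = y0_0),
               lower = c(A1 = -Inf, t1 = 1e-9, y0 = -Inf),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    sse0 <- sum((y - (A1_0 * exp(-x / t1_0) + y0_0))^2)
    return(structure(list(y0 = y0_0, A1 = A1_0, t1 = t1_0,
                          sse = sse0, converged = FALSE),
                     class = "escape_curve_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(y0 = unname(cf["y0"]), A1 = unname(cf["A1"]), t1 = unname(cf["t1"]),
         sse = sum(stats::resid(fit)^2), converged = TRUE),
    class = "escape_curve_fit"
  )
}

#' @export
print.escape_curve_fit <- function(x, ...) {
  cat(sprintf("<escape_curve_fit> y0=%.3f A1=%.3f t1=%.3f s sse=%.3g%s\n",
              x$y0, x$A1, x$t1, x$sse,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Linear trend of beta against exit width
#'
#' Ordinary least-squares line of the fitted decay scale beta on the exit
#' width d. In the real experiments beta decreases with d (negative slope).
#'
#' @param points A data frame with columns `width_cm` and `beta_s` (or a
#'   two-column matrix/data frame in that order), one point per width.
#' @return A `trend_fit` with `slope` (s/cm), `intercept` (s), `r_squared`.
#' @export
beta_trend <- function(points) {
  points <- as.data.frame(points)
  if (ncol(points) >= 2L && !all(c("width_cm", "beta_s") %in% names(points))) {
    names(points)[1:2] <- c("width_cm", "beta_s")
  }
  w <- as.numeric(points$width_cm)
  b <- as.numeric(points$beta_s)
  if (length(unique(w)) < 2L) {
    stop("domain error: beta trend needs at least 2 distinct exit widths",
         call. = FALSE)
  }
  fit <- stats::lm(b ~ w)
  sst <- sum((b - mean(b))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sum(stats::resid(fit)^2) / sst))
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope=%.4g intercept=%.4g r^2=%.3f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
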