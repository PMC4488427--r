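#' Synthetic egress experiments
#'
#' The generator emulates the statistical structure the analysis assumes:
#' per trial, 30 +/- 2 agents; under the repellent every agent escapes, under
#' the control each agent escapes independently with a small probability;
#' inter-escape intervals are i.i.d. exponential with a width-dependent scale
#' beta, rounded to a 25 frames-per-second video grid (0.04 s); escape times
#' are the cumulative sums, with the first escape at time zero.
#'
#' Default betas per width are the decay scales fitted to the real
#' experiments (0.5 cm -> 3.17 s down to 3.0 cm -> 1.50 s), so a default
#' synthetic experiment is quantitatively comparable with the original study
#' design: 6 exit widths x 6 repellent repetitions + 3 control repetitions.
#'
#' @name synthetic-egress
NULL

.default_beta_by_width <- c(
  "0.5" = 3.17, "1" = 2.95, "1.5" = 2.79,
  "2" = 1.81, "2.5" = 1.47, "3" = 1.50
)

width_key <- function(width) {
  vapply(as.numeric(width), function(w) format(w, trim = TRUE), character(1))
}

#' Build a simulation configuration
#'
#' @param widths_cm Exit widths (cm).
#' @param beta_by_width Named numeric vector, width -> exponential scale beta
#'   in seconds (names as produced by `format(width)`, e.g. `"0.5"`, `"1"`).
#' @param reps_repellent Repetitions per width under the repellent.
#' @param reps_control Repetitions per width under the control.
#' @param n_agents_mean Mean number of agents placed in the chamber.
#' @param n_agents_jitter Trial-to-trial jitter, uniform on
#'   `n_agents_mean` +/- `n_agents_jitter`.
#' @param frame_dt_s Video time grid in seconds (25 fps = 0.04 s).
#' @param control_escape_prob Per-agent escape probability under the control.
#' @param seed Root seed; every trial's randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(widths_cm = seq(0.5, 3.0, by = 0.5),
                              beta_by_width = .default_beta_by_width,
                              reps_repellent = 6L,
                              reps_control = 3L,
                              n_agents_mean = 30L,
                              n_agents_jitter = 2L,
                              frame_dt_s = 0.04,
                              control_escape_prob = 0.1,
                              seed = 1L) {
  beta_by_width <- unlist(beta_by_width)
  if (is.null(names(beta_by_width)) || any(!nzchar(names(beta_by_width)))) {
    stop("configuration error: beta_by_width must be named by width",
         call. = FALSE)
  }
  if (any(beta_by_width <= 0)) {
    stop("configuration error: all beta values must be positive",
         call. = FALSE)
  }
  if (frame_dt_s <= 0) {
    stop("configuration error: frame_dt_s must be positive", call. = FALSE)
  }
  if (control_escape_prob < 0 || control_escape_prob > 1) {
    stop("configuration error: control_escape_prob must be in [0, 1]",
         call. = FALSE)
  }
  missing_beta <- setdiff(width_key(widths_cm), names(beta_by_width))
  if (length(missing_beta)) {
    stop("configuration error: no beta defined for width(s): ",
         paste(missing_beta, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      widths_cm = as.numeric(widths_cm),
      beta_by_width = beta_by_width,
      reps_repellent = as.integer(reps_repellent),
      reps_control = as.integer(reps_control),
      n_agents_mean = as.integer(n_agents_mean),
      n_agents_jitter = as.integer(n_agents_jitter),
      frame_dt_s = as.numeric(frame_dt_s),
      control_escape_prob = as.numeric(control_escape_prob),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Deterministic sub-seed from a root seed and integer tokens; arithmetic stays
# below 2^53 so the double-precision modular reduction is exact.
derive_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1
  s <- as.numeric(root) %% m
  for (tok in c(...)) {
    s <- (s * 48271 + as.numeric(tok) + 1) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one trial
#'
#' Deterministic given `(config, width, condition, stream)`: the number of
#' agents is drawn uniformly on `n_agents_mean` +/- `n_agents_jitter`; the
#' escaper count is all agents (repellent) or Binomial(n, control_escape_prob)
#' (control); intervals are i.i.d. exponential with scale `beta(width)`,
#' rounded to the frame grid; times are their cumulative sum with a leading 0.
#'
#' @param config A [simulation_config()].
#' @param width Exit width (cm), must have a beta in the config.
#' @param condition `"repellent"` or `"control"`.
#' @param stream Integer seed for this trial's randomness; by default derived
#'   from the config seed, width, condition and `rep_index`.
#' @param rep_index Repetition number, used for the trial id and the default
#'   stream derivation.
#' @return An [egress_series()].
#' @export
simulate_series <- function(config, width, condition, stream = NULL,
                            rep_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  condition <- normalize_condition(condition)
  key <- width_key(width)
  if (!key %in% names(config$beta_by_width)) {
    stop("configuration error: no beta defined for width ", key, call. = FALSE)
  }
  beta <- config$beta_by_width[[key]]
  if (is.null(stream)) {
    widx <- match(key, width_key(config$widths_cm))
    if (is.na(widx)) widx <- 1000L + round(100 * as.numeric(width))
    stream <- derive_seed(config$seed, widx,
                          match(condition, .conditions), rep_index)
  }
  with_seed(stream, {
    j <- config$n_agents_jitter
    n <- config$n_agents_mean + sample.int(2L * j + 1L, 1L) - j - 1L
    k <- if (condition == "repellent") n
         else stats::rbinom(1L, n, config$control_escape_prob)
    times <- if (k < 1L) numeric(0) else if (k == 1L) 0 else {
      iv <- stats::rexp(k - 1L, rate = 1 / beta)
      iv <- round(iv / config$frame_dt_s) * config$frame_dt_s
      c(0, cumsum(iv))
    }
    egress_series(
      trial_id = sprintf("w%s_%s_r%02d", key, condition, rep_index),
      condition = condition, exit_width_cm = width,
      times_s = times, n_initial = n
    )
  })
}

#' Simulate a full experiment
#'
#' `reps_repellent` repellent trials plus `reps_control` control trials per
#' width, with unique trial ids encoding width, condition and repetition.
#' Each trial's random stream is derived from `(seed, width, condition, rep)`,
#' so any subset is reproducible in isolation.
#'
#' @param config A [simulation_config()].
#' @return An [egress_dataset()].
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  series <- list()
  for (w in config$widths_cm) {
    for (r in seq_len(config$reps_repellent)) {
      series[[length(series) + 1L]] <-
        simulate_series(config, w, "repellent", rep_index = r)
    }
    for (r in seq_len(config$reps_control)) {
      series[[length(series) + 1L]] <-
        simulate_series(config, w, "control", rep_index = r)
    }
  }
  egress_dataset(series,
                 provenance = sprintf("synthetic (seed %d)", config$seed))
}
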