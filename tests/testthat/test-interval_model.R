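series_of <- function(times, width = 0.5, cond = "repellent") {
  egress_series("t", cond, width, times, n_initial = max(30L, length(times)))
}

test_that("intervals are successive differences; ties and degenerates handled", {
  expect_equal(compute_intervals(series_of(c(0, 1.2, 3.0)))$intervals_s,
               c(1.2, 1.8))
  expect_equal(compute_intervals(series_of(0))$intervals_s, numeric(0))
  expect_equal(compute_intervals(series_of(c(0, 0, 2)))$intervals_s, c(0, 2))

  # cumulative sum of intervals reconstructs the times exactly
  for (seed in 1:5) {
    set.seed(seed)
    t <- c(0, cumsum(round(rexp(20, 1 / 2) / 0.04) * 0.04))
    iv <- compute_intervals(series_of(t))$intervals_s
    expect_identical(c(0, cumsum(iv)), t)
  }
})

test_that("pooling concatenates within one width and condition", {
  s1 <- compute_intervals(series_of(c(0, 1, 3)))
  s2 <- compute_intervals(series_of(c(0, 3)))
  pooled <- pool_intervals(list(s1, s2))
  expect_equal(pooled$intervals_s, c(1, 2, 3))
  expect_identical(pooled$source, "pooled")

  expect_equal(pool_intervals(list(s1))$intervals_s, s1$intervals_s)
  s3 <- compute_intervals(series_of(c(0, 1), width = 1.0))
  expect_error(pool_intervals(list(s1, s3)), "mixed exit widths")
  s4 <- compute_intervals(series_of(c(0, 1), cond = "control"))
  expect_error(pool_intervals(list(s1, s4)), "mixed conditions")
})

test_that("mean interval and mean flow rate Q are reciprocal", {
  set123 <- pool_intervals(list(compute_intervals(series_of(c(0, 1, 3, 6)))))
  expect_identical(mean_interval(set123), 2)
  expect_identical(mean_flow_rate(set123), 0.5)

  # Q * mean interval == 1 on random sets
  for (seed in 1:10) {
    set.seed(seed)
    iv <- rexp(50, 1 / 3)
    s <- pool_intervals(list(compute_intervals(series_of(c(0, cumsum(iv))))))
    expect_lt(abs(mean_flow_rate(s) * mean_interval(s) - 1), 1e-12)
  }

  empty <- compute_intervals(series_of(0))
  expect_error(mean_interval(empty), "empty")
  zero <- compute_intervals(series_of(c(0, 0, 0)))
  expect_error(mean_flow_rate(zero), "simultaneous")
})

test_that("Sturges binning spans [0, max] and partitions the data", {
  s8 <- pool_intervals(list(compute_intervals(
    series_of(c(0, cumsum(c(1, 2, 3, 4, 5, 6, 7, 8)))))))
  h <- build_histogram(s8)                       # ceil(1 + log2 8) = 4
  expect_length(h$counts, 4L)
  expect_identical(h$bin_edges_s[1L], 0)
  expect_identical(h$bin_edges_s[length(h$bin_edges_s)], 8)
  expect_identical(sum(h$counts), h$n_total)

  h1 <- build_histogram(pool_intervals(list(compute_intervals(
    series_of(c(0, 2.5))))))                     # single interval, one bin
  expect_length(h1$counts, 1L)
  expect_identical(h1$counts, 1L)

  # counts partition the sample and are permutation-invariant
  for (seed in 1:10) {
    set.seed(seed)
    iv <- rexp(40, 1 / 2)
    a <- pool_intervals(list(compute_intervals(series_of(c(0, cumsum(iv))))))
    b <- pool_intervals(list(compute_intervals(
      series_of(c(0, cumsum(sample(iv)))))))
    ha <- build_histogram(a); hb <- build_histogram(b)
    expect_identical(sum(ha$counts), 40L)
    expect_identical(ha$counts, hb$counts)
    expect_equal(ha$bin_edges_s, hb$bin_edges_s)
  }

  expect_error(build_histogram(s8, rule = "fixed_width"), "fixed_width_s")
  hf <- build_histogram(s8, rule = "fixed_width", fixed_width_s = 3)
  expect_equal(diff(hf$bin_edges_s), rep(3, 3))
})

test_that("decay fit recovers exact model parameters", {
  mids_edges <- seq(0, 12, by = 1)
  mids <- (mids_edges[-1] + mids_edges[-13]) / 2
  freq <- 10 * exp(-mids / 3) + 0.5
  h <- structure(list(bin_edges_s = mids_edges, counts = freq, n_total = 1,
                      rule = "fixed_width", exit_width_cm = 0.5,
                      condition = "repellent"),
                 class = "interval_histogram")   # synthetic, exact frequencies
  fit <- fit_interval_frequency(h)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 10) / 10, 1e-6)
  expect_lt(abs(fit$beta - 3) / 3, 1e-6)
  expect_lt(abs(fit$epsilon - 0.5) / 0.5, 1e-6)

  h2 <- structure(list(bin_edges_s = c(0, 1, 2), counts = c(1, 1),
                       n_total = 2, rule = "sturges", exit_width_cm = 0.5,
                       condition = "repellent"),
                  class = "interval_histogram")
  expect_error(fit_interval_frequency(h2), "at least 3 bins")
})

test_that("decay fit matches the grid-search SSE oracle on random histograms", {
  for (seed in 1:10) {
    h <- random_small_histogram(seed, n = 60L, beta = 2)
    if (length(h$counts) < 3L) next
    fit <- fit_interval_frequency(h)
    oracle <- grid_fit_oracle(h)
    expect_true(fit$converged)
    expect_lte(fit$sse, oracle$sse + 1e-12)
    # beta comparable only where the oracle's profile SSE identifies it;
    # on a flat surface only the SSE comparison is meaningful
    # the lattice certifies nothing outside its own domain: a fit that
    # escapes it (flat-surface linear regime) is covered by the SSE check
    bs <- oracle_beta_set(oracle, fit$sse)
    if (bs$identified && fit$beta <= max(oracle$b_grid) &&
        fit$beta >= min(oracle$b_grid)) {
      expect_gte(fit$beta, bs$lo - 2 * oracle$beta_step)
      expect_lte(fit$beta, bs$hi + 2 * oracle$beta_step)
    }
  }
})

test_that("escape curve fit recovers the saturating model", {
  # times generated from y = A1*exp(-x/t1) + y0 with y0 = 30, A1 = -30,
  # t1 = 5: the i-th escape happens when the curve reaches i
  i <- 1:29
  x <- -5 * log((30 - i) / 30)
  fit <- fit_escape_curve(series_of(x))
  expect_true(fit$converged)
  expect_lt(abs(fit$y0 - 30) / 30, 1e-6)
  expect_lt(abs(fit$t1 - 5) / 5, 1e-6)
  # re-referencing to the first escape rescales only the amplitude
  expect_lt(abs(fit$A1 - (-30 * exp(-x[1] / 5))) / 30, 1e-6)

  # asymptote tracks the final escaped count on model-consistent data
  set.seed(4)
  xn <- sort(x + rnorm(29, 0, 0.02))
  fitn <- fit_escape_curve(series_of(xn))
  expect_lt(abs(fitn$y0 - 29), 1.5)

  expect_error(fit_escape_curve(series_of(c(0, 1, 2))), "at least 4")
})

test_that("beta trend is the OLS line of beta on width", {
  pts <- data.frame(width_cm = c(0.5, 1, 1.5, 2), beta_s = 4 - 0.8 * c(0.5, 1, 1.5, 2))
  tr <- beta_trend(pts)
  expect_equal(tr$slope, -0.8, tolerance = 1e-12)
  expect_equal(tr$intercept, 4, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)

  # decay scales fitted to the real experiments decrease with width
  paper_pts <- data.frame(width_cm = seq(0.5, 3, by = 0.5),
                          beta_s = c(3.17, 2.95, 2.79, 1.81, 1.47, 1.50))
  expect_lt(beta_trend(paper_pts)$slope, 0)

  expect_error(beta_trend(data.frame(width_cm = c(1, 1), beta_s = c(2, 3))),
               "distinct exit widths")
})
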