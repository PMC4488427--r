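series_of <- function(times, width = 0.5, cond = "repellent") {
  egress_series("t", cond, width, times, n_initial = max(30L, length(times)))
}

group_sizes <- function(gr) vapply(gr$groups, `[[`, integer(1), "S")

test_that("segmentation finds maximal runs below the threshold", {
  gr <- segment_groups(series_of(c(0, 1, 2, 10, 11)), threshold_s = 5)
  expect_identical(group_sizes(gr), c(3L, 2L))

  # threshold below every interval: all singletons
  gr1 <- segment_groups(series_of(c(0, 2, 4, 6)), threshold_s = 1)
  expect_identical(group_sizes(gr1), rep(1L, 4L))

  # an interval exactly at the threshold splits (strict "below")
  gr2 <- segment_groups(series_of(c(0, 5, 6)), threshold_s = 5)
  expect_identical(group_sizes(gr2), c(1L, 2L))

  expect_error(segment_groups(series_of(c(0, 1)), threshold_s = 0),
               "positive")
})

test_that("segmentation matches exhaustive run enumeration on 1000 random series", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    times <- c(0, cumsum(round(rexp(n - 1, 1) / 0.04) * 0.04))
    thr <- runif(1, 0.1, 3)
    gr <- segment_groups(series_of(times), thr)
    oracle <- brute_force_runs(times, thr)
    expect_identical(lapply(gr$groups, `[[`, "times_s"), oracle)
    # partition: group sizes sum to the event count
    expect_identical(sum(group_sizes(gr)), length(times))
  }
})

test_that("raising the threshold never increases the group count", {
  set.seed(7)
  for (i in 1:50) {
    times <- c(0, cumsum(round(rexp(25, 1 / 2) / 0.04) * 0.04))
    s <- series_of(times)
    counts <- vapply(seq(0.2, 6, by = 0.2), function(thr) {
      length(segment_groups(s, thr)$groups)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("Q_S = (N-1)/t_S with the documented singularity", {
  gr <- segment_groups(series_of(c(0, 1, 2)), threshold_s = 5)
  expect_identical(group_flow_rate(gr$groups[[1]]), 1)

  gr2 <- segment_groups(series_of(c(0, 4)), threshold_s = 5)
  expect_identical(group_flow_rate(gr2$groups[[1]]), 0.25)

  # simultaneous pair: t_S = 0, Q_S infinite -> singularity error
  gr3 <- segment_groups(series_of(c(5, 5) - 5), threshold_s = 5)
  expect_error(group_flow_rate(gr3$groups[[1]]), "singularity")

  single <- segment_groups(series_of(0), threshold_s = 5)$groups[[1]]
  expect_error(group_flow_rate(single), "two members")
})

test_that("within-group intervals below threshold imply Q_S > 1/threshold", {
  set.seed(21)
  for (i in 1:30) {
    times <- c(0, cumsum(round(rexp(28, 1 / 2) / 0.04) * 0.04))
    thr <- runif(1, 0.5, 4)
    for (g in segment_groups(series_of(times), thr)$groups) {
      if (g$S >= 2L && g$tS_s > 0) {
        expect_lt(g$tS_s, (g$S - 1) * thr)
        expect_gt(group_flow_rate(g), 1 / thr)
      }
    }
  }
})

test_that("collect_group_stats filters, excludes singular groups, and counts them", {
  ds <- egress_dataset(list(
    egress_series("t1", "repellent", 0.5, c(0, 1, 2, 10, 11))
  ))
  rows <- collect_group_stats(ds, thresholds = c("0.5" = 5), min_size = 2L)
  expect_identical(rows$S, c(3L, 2L))
  expect_equal(rows$QS, c(1, 1))
  expect_identical(attr(rows, "n_singular"), 0L)

  rows3 <- collect_group_stats(ds, thresholds = c("0.5" = 5), min_size = 3L)
  expect_identical(nrow(rows3), 1L)
  expect_identical(rows3$S, 3L)

  # a zero-span pair is excluded and counted
  ds2 <- egress_dataset(list(
    egress_series("t1", "repellent", 0.5, c(0, 0, 10, 11, 12))
  ))
  rows2 <- collect_group_stats(ds2, thresholds = c("0.5" = 5), min_size = 2L)
  expect_identical(attr(rows2, "n_singular"), 1L)
  expect_identical(rows2$S, 3L)

  expect_error(collect_group_stats(ds, thresholds = c("1" = 5)),
               "no threshold defined for width 0.5")
  expect_error(collect_group_stats(ds, thresholds = c("0.5" = 5),
                                   min_size = 1L), "at least 2")
})

test_that("expectation thresholds are the pooled mean intervals per width", {
  ds <- egress_dataset(list(
    egress_series("a", "repellent", 0.5, c(0, 2, 6)),    # intervals 2, 4
    egress_series("b", "repellent", 0.5, c(0, 6)),       # interval 6
    egress_series("c", "repellent", 1.0, c(0, 1, 2))     # intervals 1, 1
  ))
  th <- expectation_thresholds(ds)
  expect_equal(th[["0.5"]], 4)
  expect_equal(th[["1"]], 1)
})

test_that("mean group flow rate averages qualifying groups", {
  rows <- tibble::tibble(S = c(3L, 4L, 2L), QS = c(1, 3, 99))
  expect_identical(mean_group_flow_rate(rows, min_size = 3L), 2)
  expect_identical(mean_group_flow_rate(rows[2, ], min_size = 3L), 3)
  expect_error(mean_group_flow_rate(rows[rows$S > 4, ], min_size = 3L),
               "no qualifying groups")
})

test_that("mean Q_S (N>=3) exceeds Q on paper-like synthetic data", {
  ds <- simulate_experiment(simulation_config(seed = 12L))
  th <- expectation_thresholds(ds)
  rows <- collect_group_stats(ds, thresholds = th, min_size = 3L)
  for (w in ds$widths) {
    q <- mean_flow_rate(pooled_intervals(ds, w))
    mqs <- mean_group_flow_rate(rows[abs(rows$width_cm - w) < 1e-9, ],
                                min_size = 3L)
    # every within-group interval is below the threshold 1/Q by construction
    expect_gt(mqs, q)
  }
})
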