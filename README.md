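# egressr

Analysis of single-exit egress experiments with ants under a repellent: a
known number of ants (~30) is placed in a small chamber with one exit of
width *d* (0.5–3.0 cm), a repellent drives them out, and a 25 fps video
records when each individual completely passes the exit. egressr turns the
resulting per-ant escape times into the field's standard egress statistics,
for behavioral ecologists and collective-motion researchers working with
this kind of event-time data.

## What it computes

Each trial is an ordered vector of escape times, re-referenced so the first
escape is time zero. From the inter-escape intervals (headways)
Δt within a trial, pooled over the repetitions of one width, the package
computes:

* **Interval-frequency decay.** Per width, the histogram of pooled intervals
  is fitted with
  *p<sub>f</sub>(Δt) = α·exp(−Δt/β) + ε* by least squares; the decay scale β
  (seconds) characterises the distribution and decreases with exit width
  (an OLS trend line of β on *d* quantifies this).
* **Mean interval and mean flow rate.** The expectation of the pooled
  intervals and its reciprocal *Q = 1/mean(Δt)* (ants/s).
* **Cumulative escape curve.** Per trial, *y(x) = A₁·exp(−x/t₁) + y₀*
  fitted to the escaped count over time.
* **Group (burst) segmentation and Q_S.** Consecutive escapers form a group
  while their interval stays strictly below the width's expectation
  threshold (the pooled mean interval). A group of *N* members spanning
  *t_S = t_N − t₁* has group flow rate *Q_S = (N−1)/t_S*; simultaneous pairs
  (*t_S = 0*) are excluded and counted. Default qualifying size: N ≥ 2 at the
  0.5 cm exit, N ≥ 3 otherwise.
* **Comparison statistics.** Pairwise Welch t tests of interval samples
  across widths with star annotation (strictly *p* < 0.05 / 0.01 / 0.001),
  the S–Q_S Pearson correlation, and repellent-vs-control comparisons of
  per-trial escaped counts.

A seeded synthetic generator reproduces the experimental design (6 widths ×
6 repellent + 3 control repetitions, 30 ± 2 agents, exponential intervals on
a 0.04 s video grid), so the entire pipeline runs and is tested without any
external data. See `vignettes/egress-analysis.Rmd` for the model details,
parameter meanings, and what the generator does and does not emulate.

## Worked example

```r
library(egressr)

config  <- simulation_config(seed = 42)   # paper-design defaults
dataset <- simulate_experiment(config)    # 54 trials
report  <- run_analysis(dataset)

report$per_width[, c("width_cm", "n_intervals", "mean_interval_s",
                     "Q", "beta", "converged")]
#> # A tibble: 6 × 6
#>   width_cm n_intervals mean_interval_s     Q  beta converged
#>      <dbl>       <int>           <dbl> <dbl> <dbl> <lgl>
#> 1      0.5         166            2.83 0.353  2.76 TRUE
#> 2      1           175            2.84 0.352  2.28 TRUE
#> 3      1.5         170            2.81 0.356  3.34 TRUE
#> 4      2           179            1.88 0.531  2.12 TRUE
#> 5      2.5         175            1.47 0.678  1.36 TRUE
#> 6      3           176            1.42 0.704  1.19 TRUE

round(report$beta_trend$slope, 3)
#> [1] -0.676
```

Each row summarises one exit width: `n_intervals` pooled headways over six
repetitions, their mean (s), the mean flow rate `Q` (ants/s), and the fitted
decay scale `beta` (s). The negative trend slope says wider exits have
faster-decaying interval distributions (shorter waits dominate). The group
statistics show the burst structure:

```r
report$group_summary
#> # A tibble: 6 × 5
#>   width_cm n_groups min_size mean_QS     Q
#>      <dbl>    <int>    <int>   <dbl> <dbl>
#> 1      0.5       50        2    1.49 0.353
#> 2      1         27        3    1.33 0.352
#> 3      1.5       28        3    1.03 0.356
#> 4      2         32        3    1.74 0.531
#> 5      2.5       26        3    1.95 0.678
#> 6      3         23        3    2.23 0.704
```

`mean_QS` (the mean within-burst flow rate) exceeds `Q` at every width, as
it must: groups are by construction the below-threshold stretches of the
flow.

Real data enter through the canonical event table (CSV/TSV with columns
`trial_id, condition, exit_width_cm, egress_time_s[, n_initial]`, any time
reference) via `read_egress_table()`; XLSX sheets are imported with an
explicit column mapping. The same pipeline is scriptable:

```sh
egressr simulate --seed 42 --out egress.csv
egressr analyze egress.csv --out-dir results/
egressr report results/report.json
```

`analyze` writes tidy CSV tables and a `report.json` whose layout is
described by the schema in `inst/schema/report-schema.json`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch: it generates the
default seeded synthetic experiment, runs every pipeline stage (interval
statistics, decay fits, β trend, group segmentation and Q_S summaries,
comparison tests), writes the full report next to the target file, and
writes the target JSON to `--out`.
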