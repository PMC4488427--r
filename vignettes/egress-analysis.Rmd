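---
title: "Analysing single-exit egress dynamics with egressr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing single-exit egress dynamics with egressr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egressr)
```

## The experimental system and its data model

egressr analyses *egress experiments*: a known number of ants (about 30) is
placed in a small single-exit chamber, a repellent drives them out, and a
25 fps video records the time at which each individual completely passes the
exit. The exit width $d$ is varied across trials (0.5–3.0 cm in 0.5 cm
steps); each width is repeated six times under the repellent and three times
under a water control, in which only a small fraction of ants leaves.

The unit of data is one trial's ordered escape times in seconds, relative to
the first escape ("time zero" is the instant the first ant completely passes
the exit). Everything downstream is computed from the *inter-escape
intervals* (headways) $\Delta t_i = t_{i+1} - t_i$ within a trial, pooled
over the repetitions of one width.

## The interval-frequency model

Pooled interval histograms decay roughly exponentially in $\Delta t$. The
package fits, separately for each exit width,

$$p_f(\Delta t) = \alpha\, e^{-\Delta t/\beta} + \varepsilon,$$

by unweighted least squares on (bin midpoint, relative frequency) pairs,
where $p_f$ is the fraction of intervals in a bin. $\beta$ (seconds) is the
decay scale — larger $\beta$ means long waits between escapes are more
common — and is the main width-dependent quantity: it decreases as the exit
widens. $\alpha$ sets the short-interval amplitude and $\varepsilon$ is a
small offset absorbing binning and tail effects; neither is interpreted
further.

Numerical choices, all of which matter for reproducibility:

* **Binning.** Sturges' rule by default, $k = \lceil 1 + \log_2 n \rceil$
  equal-width bins spanning $[0, \max \Delta t]$, left-closed with a
  right-closed last bin. The rule is configurable (`scott`, `fixed_width`)
  because $\hat\beta$ depends on it; the source analyses cite a statistics
  textbook without an explicit rule, and Sturges is the common textbook
  default.
* **Starting values and optimisation.** The fit is multi-start: a
  moment-based start ($\varepsilon_0 = \min p_f$,
  $\alpha_0 = \max p_f - \varepsilon_0$, $\beta_0 =$ the binned mean
  interval), a log-linear regression start (slope of
  $\log(p_f - \varepsilon_0)$ on the midpoints), and a coarse span/3 start.
  Each start is refined with `nls` (port algorithm, $\alpha \ge 0$,
  $\beta > 0$) and a Nelder–Mead polish; the lowest-SSE solution wins. The
  polish is not cosmetic: with a free offset the SSE surface can be almost
  flat in $\beta$ (as $\beta \to \infty$ the model degenerates to a straight
  line), where Gauss–Newton alone reports false convergence.
* **Non-convergence** is recorded in the `converged` flag of the returned
  fit, never raised as an error, so a batch analysis survives a degenerate
  width.

The *mean* interval (the "mathematical expectation") is computed from the
raw pooled intervals, not from the histogram: the raw mean is well defined
and binning-independent. Its reciprocal is the mean flow rate
$Q = 1/\overline{\Delta t}$ in ants per second.

The cumulative escape curve of one trial (count escaped vs time, a
right-continuous step sampled at the event times) is fitted with
$y(x) = A_1 e^{-x/t_1} + y_0$, the saturating form with $A_1 < 0$ whose
asymptote $y_0$ approximates the final escaped count. The trend of $\beta$
against $d$ is an ordinary least-squares line.

## Group segmentation and the group flow rate

Consecutive escapers belong to one *group* (burst) when their interval is
**strictly below** the expectation threshold for that width — the pooled
mean interval, recomputed from the data under analysis (a config override
can pin external values). An interval exactly equal to the threshold splits
the group; this boundary convention is tested explicitly. Segmentation
yields maximal runs, singletons included, partitioning the trial's events.

For a group of $N$ members spanning $t_S = t_N - t_1$ seconds the group flow
rate is

$$Q_S = \frac{N-1}{t_S}.$$

A two-member group escaping simultaneously on the video grid has $t_S = 0$
and an infinite $Q_S$; such groups are excluded from summaries and counted
separately rather than propagated. By default groups of $N \ge 2$ qualify at
the narrowest (0.5 cm) exit, where the opening passes one ant at a time, and
$N \ge 3$ at wider exits, where simultaneous pairs occur; the policy is
configurable. Because every within-group interval is below the threshold
$1/Q$, the mean $Q_S$ necessarily exceeds $Q$ at the same width — the
package's tests use this as a consistency check, not a discovery.

## Comparison statistics

Pooled interval samples of two widths are compared with a two-sample t test
— Welch's unequal-variance variant by default, since the pooled samples
differ in size and spread and the original analysis does not state its
variance assumption; a pooled-variance variant is available. Stars encode
two-tailed p-values with strict thresholds: `***` $p<0.001$, `**` $p<0.01$,
`*` $p<0.05$. No multiple-testing correction is applied by default, matching
the original pairwise analysis; Bonferroni/Holm are available and stars then
follow the adjusted values. The association between group size $S$ and $Q_S$
is summarised by the Pearson correlation with the usual $t$-transform
p-value on $n-2$ degrees of freedom. Escaped-count differences between
repellent and control trials at one width use the same t machinery on
per-trial counts. One deliberate relaxation: the t test errors only when
*both* samples are constant — a constant control triple (e.g. three trials
with 3 escapes each) is valid data with a well-defined Welch statistic.

## The synthetic generator: what it emulates, what it does not

`simulate_experiment()` reproduces the design of the real experiments: 6
widths × (6 repellent + 3 control) trials, $30 \pm 2$ agents drawn uniformly
per trial, intervals i.i.d. exponential with the width's scale
$\beta$ — defaulting to the scales fitted to the real data (3.17, 2.95,
2.79, 1.81, 1.47, 1.50 s for 0.5–3.0 cm) — rounded to the 0.04 s video
grid, and cumulated from time zero. Under the control each agent escapes
independently with probability 0.1, chosen to match the observation that
only a few ants leave without the repellent (no count is printed for the
control; ~3 of 30 is a realistic order). Randomness is a single root seed
with per-trial streams derived from (seed, width, condition, repetition), so
any subset regenerates identically in isolation.

The $\varepsilon$ offset of the fitted model is treated as a fitting
nuisance, not as part of the generative law: the pure exponential is the
simplest process whose interval histogram matches the observed decay, and a
generative offset would put probability on arbitrarily long intervals.

Deliberate unrealisms, which bound what a green test establishes:

* Intervals are i.i.d., so the generator's cumulative escape curves are
  approximately linear, not saturating as real trials are (real intervals
  lengthen late in a trial). Escape-curve fits are therefore tested on
  model-consistent data, and nothing is asserted about curve fits on
  generator output.
* Groups arise purely from exponential clustering; the generator encodes no
  behavioral mechanism, so the synthetic $S$–$Q_S$ correlation is ~0 and the
  positive correlation seen in real 0.5 cm data is not a testable property
  here.
* No spatial motion, no repellent-concentration dynamics, no exit-geometry
  physics: simultaneous escapes arise only from grid rounding.

Parameter recovery on this stated world is the core calibration test: with
the default design, the median relative error of $\hat\beta$ across widths
and a fixed 5-seed battery is below 15%, and of the mean interval
(estimating $\beta$, the exponential mean) below 10%. A single seed's
median is itself noisy — per-width sampling error is ~8% SD at ~175 pooled
intervals — which is why the criterion is evaluated over a seed battery.

## Degenerate inputs and tie-breaks

* Empty interval sets: `mean_interval()` and `build_histogram()` raise
  domain errors; an all-zero set (every escape simultaneous) gets a single
  degenerate bin and an undefined flow rate.
* Fewer than 3 bins cannot support a 3-parameter decay fit (error); fewer
  than 4 events cannot support the escape curve (error).
* Trials with fewer than 2 events contribute no intervals and no groups.
* Input times may be absolute; the reader sorts and re-references each trial
  so its first escape is 0. Times are kept as real seconds — no snapping to
  the 0.04 s grid on input, since transcribed real data may not be
  grid-aligned.
* XLSX import never guesses the sheet layout: an explicit column mapping is
  required.

## Worked example

```{r example, eval = FALSE}
library(egressr)

config <- simulation_config(seed = 42)
dataset <- simulate_experiment(config)
report <- run_analysis(dataset)

report$per_width[, c("width_cm", "n_intervals", "mean_interval_s",
                     "Q", "beta", "converged")]
report$beta_trend$slope      # negative: wider exits decay faster
report$group_summary         # mean Q_S (N >= 3) vs Q per width
```

The same pipeline runs from a shell:

```sh
egressr simulate --seed 42 --out egress.csv
egressr analyze egress.csv --out-dir results/
egressr report results/report.json
```

## Known limitations

* The exponential-decay fit is a descriptive model; no model comparison
  against power laws or other families is performed.
* $\hat\beta$ depends on the binning rule; per-width estimates at the
  experimental sample sizes (~175 pooled intervals) carry sampling noise of
  order 10–20%.
* Thresholds derived from the analysed data make the segmentation mildly
  circular (the threshold moves with the sample); pin thresholds via the
  `thresholds` option when comparing across datasets.
* Whether real inter-escape intervals are serially correlated is unknown;
  the i.i.d. assumption lives only in the synthetic generator, not in the
  analysis.
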