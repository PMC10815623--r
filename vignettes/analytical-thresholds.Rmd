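---
title: "Deriving analytical thresholds from negative-control baselines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving analytical thresholds from negative-control baselines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strbaseline)
```

## The problem

STR genotyping by capillary electrophoresis reports every fluorescence peak
above an *analytical threshold* (AT), the minimum height in relative
fluorescence units (RFU) at and above which a peak is considered
distinguishable from baseline noise. Kit manufacturers recommend
conservative static values (here represented by `AT_ori` = 175 RFU). For
low-template DNA (tens of picograms), true allelic peaks routinely sit far
below such a threshold, so a conservative AT trades false positives (noise
and artifacts labelled as peaks, Type I) for allele dropout (Type II) very
unfavourably. The alternative is to measure the laboratory's own baseline —
the signals of amplification negative controls — and to place the AT just
above that baseline.

`strbaseline` implements that workflow end to end: parsing sizing-table
exports, cleaning them, summarising per-dye baselines, computing five
published AT estimators, and scoring any choice of threshold against a
reference genotype.

## The five estimators

Let $\bar Y_n$ and $s_{Y,n}$ be the mean and sample standard deviation
(n−1 denominator) of the pooled negative signal heights of one dye, $n_n$
the number of negative-control injections pooled, and $\upsilon$, $\tau$
the mean and standard deviation of the natural log of the heights.

* $AT_1 = \bar Y_n + k\, s_{Y,n}$, with $k = 3$;
* $AT_2 = \bar Y_n + t_{\alpha,\nu}\, s_{Y,n} / \sqrt{n_n}$ — a one-sided
  upper confidence bound on the *mean* of the noise;
* $AT_3 = \bar Y_n + t_{\alpha,\nu} \sqrt{1 + 1/n_n}\; s_{Y,n}$ — a
  one-sided prediction bound for a *new* noise observation, correcting for
  the uncertainty of the estimated mean;
* $AT_4$ = the 99th percentile of the pooled heights (the value separating
  99 % of the negative signals from the rest);
* $AT_5 = e^{\upsilon + k\tau}$, with $k = 3$ — the same exclusion bound
  computed under a lognormal noise model.

$AT_2$ bounds a mean, so it shrinks with $\sqrt{n_n}$ and is always the
smallest; $AT_5$ responds to the right skew of RFU noise and is
systematically the largest. Because baseline heights are genuinely
right-skewed, $AT_5$'s model is the best-matched of the five, and in the
package's end-to-end evaluations it is the method most often closest to the
ideal ROC corner at the higher template amounts.

### Parameter conventions

Several constants are conventions that the estimator definitions leave
open; the package fixes them once, as arguments of `threshold_params()`:

* `alpha = 0.99`, one-sided, with $\nu = n_n - 1$ degrees of freedom for
  the t-based rules. The confidence level is not dictated by the formulas
  themselves; 0.99 is chosen for coherence with the 99 % separation of
  $AT_4$ and the $k = 3$ (≈ 99.7 %) convention of $AT_1$/$AT_5$.
* `nn` counts negative-control *injections*, even though the mean and SD
  pool all signals across injections. This mixed convention mirrors how
  these estimators are used in practice (thresholds quoted "based on nine
  negative controls").
* $\tau$ in $AT_5$ is the *standard deviation* of the log heights. Treating
  it as a variance would invert the empirical ordering in which $AT_5$ is
  the largest method, so the SD reading is adopted.
* Quantiles use linear interpolation between order statistics
  (`quantile(type = 7)`).
* Reported thresholds are rounded *up* to whole RFU (`ceil_int`), which is
  the conservative direction for noise exclusion; raw values are retained
  in the `"raw"` attribute. `rounding = "none"` disables this.

## The cleaning cascade

Negative controls, before baseline summary:

1. `filter_read_region()` — keep sizes inside the manufacturer's read
   region, closed on both ends.
2. `filter_ils_adjacent()` — remove signals within 2 bp (distance ≤ 2.0,
   measured in bp, not scan points) of an internal-lane-standard fragment,
   because ILS fragments bleed into neighbouring dyes; the ILS channel
   itself never enters the analysis.

Low-template positives, before evaluation (`prepare_profile()`):

1. `screen_locus_positions()` — keep peaks inside a marker interval on
   their own dye and annotate the marker. An "OL" (off-ladder) allele label
   does not itself cause removal; position decides.
2. `remove_pullup()` — remove peaks that share a position (± 0.3 bp) with
   an allelic peak in *another* dye and are ≤ 5 % of its height. Both
   bounds are inclusive, and when several allelic peaks qualify the tallest
   is used — the most conservative removal. The allelic reference peaks
   are the same injection's peaks that match the reference genotype.

Every filter returns a `filter_report` whose counts reconcile exactly
(input = removed + retained) with per-record reason tags, so the cascade is
auditable. All filters are idempotent, and enlarging a removal window never
grows the retained set; both properties are enforced by tests.

## Evaluation against a reference genotype

`classify_peaks()` labels each cleaned record *allelic* when its size falls
within ± 0.5 bp of the bin center of an expected allele at its marker, else
*non-allelic*; expected alleles with no matching record are dropouts.
Conventions, fixed deliberately:

* A homozygous marker contributes **one** expected allele — detection is
  presence/absence, with no heterozygote-balance or peak-height-ratio
  logic.
* `tpr = detected / expected`. The false-positive rate has no natural
  denominator in this design (there is no finite set of "negative bins"),
  so the package defines `fpr = min(1, non_allelic / expected)`: the
  artifact tally normalised by the same denominator as the dropouts and
  capped at 1. This makes the two error terms commensurate and gives the
  total error `(1 - tpr) + fpr` its range of [0, 2], with the value 1.0
  as the "complete dropout, no artifacts" floor that a very high static
  threshold produces at the lowest template. This is an explicit package
  convention, not an inference about how any other implementation
  normalised its rates.
* `sweep_thresholds()` varies the AT over 1–200 RFU. Internally it
  pre-computes, per replicate, the tallest matching peak height for every
  expected allele and all artifact heights; thresholding then reduces to
  comparisons. This is exactly equivalent to `apply_threshold()` followed
  by `classify_peaks()` (a test asserts the equivalence) but makes the
  200-point sweep cheap.
* `roc_points()` selects, per condition, the method minimising the
  Euclidean distance to the ideal corner (0, 1), breaking ties toward the
  lower false-positive rate.

## The synthetic-data generator

No instrument data ships with the package; `simulation_config()`,
`simulate_negative()`, `simulate_positive()` and `generate_study()`
generate sizing tables with the statistical structure the method assumes:

* **Baseline noise** per dye: Poisson(10) signals per injection, sizes
  uniform over the read region, heights lognormal. The per-dye defaults
  (log-mean 2.00–2.40, log-SD 0.30–0.33) give mean heights of roughly
  7–11 RFU with the blue channel lowest, reproducing the ordering and the
  right-skewed shapes seen across commercial kits; they are chosen to be
  qualitatively realistic, not fitted to any published per-dye numbers.
* **Allelic peaks**: mean height 48 RFU at 31.25 pg and 27 cycles, scaling
  linearly with template and doubling per cycle, with multiplicative
  lognormal noise (log-SD 0.5). Homozygous alleles carry both template
  copies. A peak is emitted only if its drawn height reaches 1 RFU. This
  height model is invented plumbing — the method under test only needs
  heights that move the right way with template and cycles — and all its
  parameters are exposed.
* **Artifacts**: one stutter peak per allelic peak at the n−1 repeat
  position with ratio ~ Normal(0.08, 0.03) truncated at zero, and with
  probability 0.05 a cross-dye pull-up peak at ± U(0, 0.3) bp and
  U(1, 5) % height — i.e. exactly the signature the pull-up filter
  removes.
* **Study design**: `generate_study()` emits the full factorial of the
  low-template experiment — 3 template amounts (31.25 / 15.625 /
  7.8125 pg) × 3 cycle numbers (27 / 29 / 31) × 3 PCR × 3 CE replicates
  positives (81 tables) plus 9 negatives per cycle number (27 tables).
  Each table draws from its own sub-seed derived from the study seed, so
  single tables regenerate independently and whole studies regenerate
  identically.

What the generator does **not** emulate: correlated CE replicates (each
injection is drawn independently, so between-injection variance is
slightly overstated), spikes and other sporadic artifacts, degraded-DNA
size-dependent amplification, drop-in contamination, and locus-specific
stutter ratios. Passing tests on synthetic data therefore demonstrate the
correctness and internal coherence of the computations, not the field
performance of any particular threshold on real instruments.

## Numerical and degenerate-input choices

* A dye with zero negative signals yields a flagged zero-count summary
  (`undefined_mean = TRUE`), not an error; with fewer than two signals the
  estimators refuse with an insufficient-data error, and
  `compute_all_thresholds()` flags that dye while computing the rest.
* A constant baseline (SD = 0) collapses all five estimators to the
  constant, which is the correct degenerate answer.
* The Mann–Whitney comparison (`compare_groups()`) uses the normal
  approximation with tie correction, since RFU heights are heavily tied;
  lognormality goodness of fit is a Kolmogorov–Smirnov statistic on the
  log heights against the fitted normal, reported as a descriptive
  statistic (integer quantisation makes its p value approximate).
* Problem sizes in the shipped tests and in the acceptance script are
  desk-scale by design: 9 injections × ~10 signals per dye for threshold
  ordering, 10^4–10^5 signals for parameter-recovery checks, and one full
  108-table study for the end-to-end run. These sizes are where the
  statistical properties under test stabilise while keeping the whole
  suite fast to re-run.

## A worked run

```{r example, eval = FALSE}
kit <- synth_kit()
gt  <- synth_genotype(kit)
cfg <- simulation_config(kit)

study <- generate_study(cfg, kit, gt, seed = 1)
negs <- lapply(study$tables[study$manifest$sample_id[
  study$manifest$role == "negative" & study$manifest$cycles == 27]],
  function(t) filter_ils_adjacent(filter_read_region(t, kit)$table, kit)$table)

sets <- compute_all_thresholds(negs, kit)
thresholds_table(sets)

pos <- lapply(study$tables[study$manifest$sample_id[
  study$manifest$role == "positive"]],
  function(t) prepare_profile(t, gt, kit)$table)
res <- compare_methods(sets, pos, gt, kit)
roc_points(res)$best
```

## Known limitations

* The kit and genotype fixtures are synthetic; real kit bin sets and the
  genotype of a typed control DNA must be supplied by the user for real
  casework data.
* The command-line baseline report, when run without a kit configuration,
  knows only the five basic parameters; ILS *fragment-level* proximity
  filtering then cannot run (fragment positions are unknown), and only the
  ILS channel itself is excluded.
* The false-positive-rate convention above is one defensible choice among
  several; comparisons against rates computed under a different
  normalisation are not meaningful.
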