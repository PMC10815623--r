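# strbaseline

Analytical thresholds for STR electropherograms, derived from the baseline
signals of amplification negative controls.

## What this solves

Forensic STR profiles are read above an *analytical threshold* (AT): the
minimum peak height, in relative fluorescence units (RFU), at and above
which a detected peak is distinguished from background noise. For
low-template DNA (tens of picograms), the conservative static thresholds
recommended by kit manufacturers (e.g. 175 RFU) cause massive allele
dropout, while lowering the AT indiscriminately floods the profile with
noise and artifacts. `strbaseline` is for forensic analysts and method
developers who want to set the AT from measured laboratory baselines
instead: it parses GeneMapper-style "Sizing Table" exports of negative
controls, cleans them, summarises the per-dye baseline, computes five
published AT estimators, and quantifies the dropout / artifact trade-off
of any threshold choice against a reference genotype.

With pooled negative-signal heights of one dye (mean Ȳₙ, sample SD s,
nₙ injections, log-scale mean υ and SD τ), the estimators are

* AT₁ = Ȳₙ + 3·s
* AT₂ = Ȳₙ + t(α, nₙ−1) · s / √nₙ  (one-sided bound on the noise mean)
* AT₃ = Ȳₙ + t(α, nₙ−1) · √(1 + 1/nₙ) · s  (one-sided prediction bound)
* AT₄ = 99th percentile of the pooled heights
* AT₅ = exp(υ + 3·τ)  (lognormal noise model)

AT₂ is systematically the smallest and AT₅ the largest; because baseline
noise is right-skewed, AT₅'s lognormal model is the best-matched of the
five. Threshold choices are scored by allele dropout and non-allelic peak
counts over 1–200 RFU sweeps, by ROC distance to the ideal (FPR 0, TPR 1)
corner, and by the total error rate (1 − TPR) + FPR.

A synthetic-data module (`simulation_config()`, `simulate_negative()`,
`simulate_positive()`, `generate_study()`) generates negative-control and
low-template positive sizing tables with the assumed statistical structure
(lognormal per-dye noise, template/cycle-dependent peak heights, stutter,
pull-up), so the entire pipeline is testable without instrument data.

## Worked example

```r
library(strbaseline)

kit <- synth_kit()                       # synthetic 6-channel kit (5 dyes + ILS)
cfg <- simulation_config(kit)

# nine negative-control injections, cleaned by the standard cascade
negs <- lapply(1:9, function(i) {
  t <- simulate_negative(cfg, kit, seed = 100 + i)
  filter_ils_adjacent(filter_read_region(t, kit)$table, kit)$table
})
thresholds_table(compute_all_thresholds(negs, kit))
```

```
         B   G   Y   R   P
AT_ori 175 175 175 175 175
AT1     16  21  16  23  26
AT2     11  15  11  15  17
AT3     16  21  16  23  26
AT4     14  20  15  23  28
AT5     19  28  20  28  29
```

Rows are threshold methods, columns the five analysis dyes, values in RFU:
the static threshold (175) sits an order of magnitude above every
baseline-derived value; AT₂ is the per-dye minimum and AT₅ the maximum of
the calculated methods. Evaluating the six sets on simulated low-template
profiles:

```r
gt  <- synth_genotype(kit)
study <- generate_study(cfg, kit, gt, seed = 1)      # 81 positives + 27 negatives
pos <- lapply(study$tables[study$manifest$sample_id[
  study$manifest$role == "positive"]],
  function(t) prepare_profile(t, gt, kit)$table)
res <- compare_methods(compute_all_thresholds(negs, kit), pos, gt, kit)
subset(res, template_pg == 7.8125 & cycles == 27,
       c(method, mean_dropouts, mean_non_allelic, total_error))
```

```
 method mean_dropouts mean_non_allelic total_error
 AT_ori      34.00000        0.0000000   1.0000000
    AT1      25.55556        0.1111111   0.7549020
    AT2      18.22222        2.5555556   0.6111111
    AT3      25.55556        0.1111111   0.7549020
    AT4      24.66667        0.3333333   0.7352941
    AT5      28.44444        0.0000000   0.8366013
```

At the lowest template (7.8125 pg, 27 cycles) the static threshold drops
all 34 expected alleles — total error exactly at the 1.0 complete-dropout
floor — while the baseline-derived thresholds recover several alleles at
the cost of a few artifact peaks (AT₂, the lowest, admits the most).
`roc_points(res)` then names the method closest to the ideal corner for
each (template, cycles) condition.

A command-line entry point over these functions lives at
`inst/cli/negaprocess.R` (subcommands `baseline` and `simulate`;
`--help` lists the five parameters of the baseline report: input path,
channel count including the ILS, the two read-region bounds, and the plot
x-maximum). It writes two CSV spreadsheets (per-sample signal summary,
per-dye threshold table) and a height-distribution figure.

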