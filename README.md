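# retag

Quantification and inference for **two-epoch activity-dependent
neuronal tagging experiments** — the kind of design where cells active
during a first behavioural epoch are permanently HA-tagged
(c-Fos-driven TRAP/RiboTag labeling), cells active during a second
epoch express c-Fos, and the question is whether the same cells are
recruited twice more often than chance.

The package is aimed at labs analysing immunohistochemistry cell-count
tables from such designs (e.g. repeated sleep deprivation in
hippocampal CA1) and at anyone planning one: it bundles the
quantification conventions, the overlap model, the group statistics,
and a generative simulator for validation and power analysis.

## The model

For one animal, in one quantified region, count

* `N` — DAPI+ nuclei,
* `K` — HA-tagged cells (epoch-1 active),
* `n` — c-Fos+ cells (epoch-2 active),
* `O` — double-labeled cells.

Under **random activation** (epoch 2 independent of epoch 1) the
expected overlap is

> E = n · (K / N)

and the **reactivation index**

> RI = O / E

equals 1.  Cohort inference is a one-sample t-test of per-animal RI
against 1; per-animal evidence is the one-sided hypergeometric tail
P(X ≥ O), X ~ Hypergeom(N, K, n).  Around this core the package
provides area-normalized marker densities (counts/mm², averaged over
an animal's sections), cell-type composition of activated cells,
summary-statistic t-tests (reconstructing printed t-values from
`mean ± SEM, n`), Type III two-way ANOVA and Bonferroni adjustment,
and a simulator whose reactivation bias is an odds multiplier applied
through a logistic link.

## Worked example

Simulate a repeated-SD cohort at the package defaults and test for
non-random reactivation in CA1:

```r
library(retag)
cfg    <- simConfig(seed = 42)
cells  <- simulateCohort(cfg, c("SD-SD", "NSD-NSD"))
ri     <- as.data.frame(reactivationIndex(tabulateOverlap(cells, "CA1")))
sdsd   <- ri[ri$epoch1 == "SD" & ri$epoch2 == "SD", ]
cohortRITest(sdsd$RI)
```

```
 animal_id    N   K   n  O     E    RI pct_of_tagged   p_hyper
   SD-SD_1 2000 226 280 66 31.64 2.086         29.20 1.521e-10
   SD-SD_2 2000 234 288 75 33.70 2.226         32.05 1.125e-13
   SD-SD_3 2000 211 302 69 31.86 2.166         32.70 6.115e-12
   SD-SD_4 2000 196 262 65 25.68 2.532         33.16 8.967e-15
   SD-SD_5 2000 201 272 60 27.34 2.195         29.85 1.348e-10

mean RI = 2.24 +/- 0.08 (SEM), t(4) = 16.26, p = 8.4e-05
```

Each animal's observed double-label count `O` is about twice its
random-activation expectation `E` (~30% of tagged cells re-activate),
and the cohort test rejects RI = 1 decisively — the simulated bias
(`reactBias = 2`) is recovered by the inference.

Reconstructing a published group comparison from its printed summary
statistics:

```r
tFromSummary(groupSummary("NSD", 180.64, 11.53, 5),
             groupSummary("SD",  408.39, 14.27, 6))
#> t = -12.05, df = 9, p = 7.4e-07
```

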