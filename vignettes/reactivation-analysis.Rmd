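---
title: "Quantifying non-random reactivation in two-epoch tagging experiments"
author: "retag package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying non-random reactivation in two-epoch tagging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retag)
```

## The scientific question

Activity-dependent tagging experiments ask whether the neurons recruited
by a stimulus are a stable, biased subpopulation or a random draw from
the circuit.  In the design this package supports, animals experience
two behavioural epochs (sleep deprivation, SD, or undisturbed sleep,
NSD, one week apart).  Cells active during epoch 1 are permanently
HA-tagged through c-Fos-promoter-driven recombination (a TRAP/RiboTag
strategy); cells active during epoch 2 express endogenous c-Fos, read
out by immunostain.  A double-labeled cell (HA+ and c-Fos+) was active
in both epochs.

The null hypothesis is *random activation*: epoch-2 activation is
independent of the epoch-1 tag.  For an animal with `N` DAPI+ nuclei in
the quantified region, `K` HA-tagged cells, `n` c-Fos+ cells and `O`
double-labeled cells, the expected overlap under that null is

$$E = n \cdot \frac{K}{N},$$

because a random c-Fos+ cell falls among the tagged ones with
probability `K/N`.  The **reactivation index** is

$$RI = \frac{O}{E},$$

equal to 1 under random activation and above 1 when epoch-1-active
cells are preferentially re-recruited.  Cohort-level inference is a
two-tailed one-sample t-test of the per-animal `RI` against 1
(`cohortRITest()`); per-animal evidence comes from the one-sided
hypergeometric tail `P(X >= O)` for `X ~ Hypergeom(N, K, n)`
(`hypergeomTest()`), which conditions on the observed margins.

```{r ri-example}
ri <- reactivationIndex(data.frame(
  animal_id = paste0("m", 1:4), region = "CA1",
  N = c(2000, 1800, 2200, 2100), K = c(150, 140, 180, 160),
  n = c(260, 200, 240, 230), O = c(44, 30, 47, 40)))
as.data.frame(ri)[, c("animal_id", "E", "RI", "pct_of_tagged", "p_hyper")]
cohortRITest(ri$RI)
```

## Quantification conventions

`computeDensities()` reproduces the immunohistochemistry convention of
the upstream experiments: per section, the count of marker+ cells in
the region's cell-body layer divided by the quantified area (mm²); per
animal, the **unweighted mean** over that animal's 2–3 sections.  An
area-weighted pooled estimate (total count over total area) is
available via `areaWeighted = TRUE`; it differs only when section areas
differ, and the unweighted mean is the default because sections are
averaged as equal replicates in the source protocol.  Density units are
counts/mm²; downstream tests are scale-invariant within a region, so
the unit choice affects labels only.

Cell-type composition (`cfosComposition()`) classifies c-Fos+ cells as
neurons (NeuN+), astrocytes (Sox9+) or other (neither; NeuN and Sox9
are treated as mutually exclusive, so the three fractions sum to 1
exactly).  The excitatory fraction among c-Fos+ neurons follows the
subtract-and-normalize rule `(NeuN − GAD67)/NeuN`
(`excitatoryFraction()`), with GAD67+ constrained to be a subset of
NeuN+.

`foldInduction()` returns the ratio of group means.  Note that
published fold-induction figures are sometimes computed as means of
per-animal folds and can disagree with the ratio of the printed group
means (for the CA3 comparison the printed group means give 1.54 where
the accompanying text rounds to "1.6-fold"); this package always
reports the ratio-of-means and leaves the discrepancy visible rather
than matching prose.

## Group statistics from printed summaries

Figure legends print `mean ± SEM` and `n` per group.
`tFromSummary()` reconstructs the unpaired two-tailed **pooled
(Student)** t-test from exactly those numbers (`SD = SEM·√n`, pooled
variance, `df = n_a + n_b − 2`); this is the reconstruction that
reproduces the printed t-statistics of the common commercial analysis
software from its own summaries, so pooled — not Welch — is the default
(`tFromRaw(..., variant = "welch")` is available).  Because the printed
inputs are themselves rounded to two decimals, reconstructed t-values
can differ from printed ones in the last digit (±0.01).

```{r t-example}
tFromSummary(groupSummary("NSD", 180.64, 11.53, 5),
             groupSummary("SD", 408.39, 14.27, 6))
```

`twoWayAnova()` fits the 2×2 sleep-condition × repetition design with
sum-to-zero contrasts and reports **Type III** sums of squares (via
`car::Anova`), again matching the conventions of the software used for
such designs; the choice matters because the published cohorts are
unbalanced (group sizes 5/6/6/6, error df 19).  On balanced data Type
III coincides with the classical sequential decomposition, which the
test suite verifies against textbook formulas.  Bonferroni adjustment
(`bonferroniAdjust()`) is the only multiplicity correction applied by
default, mirroring the source analyses; per-subregion multiple t-tests
are deliberately left uncorrected as in the original legends.

## The generative simulator

`simulateAnimal()`/`simulateCohort()` generate cohorts with known
ground truth so that every downstream stage is testable without any
microscopy data.  Per cell:

1. a class is drawn (neuron vs not, inhibitory among neurons, astrocyte
   among non-neurons);
2. epoch-1 activity is Bernoulli with the class- and
   condition-specific rate `act1[condition, class]`; active cells are
   HA+ with probability `tagEff`, inactive ones with the background
   rate `bgTag`;
3. epoch-2 activity uses `act2[condition, class]`, but for cells active
   in epoch 1 the probability passes through a logistic link:
   `p2' = plogis(qlogis(p2) + log(beta))`.  The reactivation bias
   `beta` is an **odds multiplier**, not a clamped `p·beta`, so any
   `beta > 0` yields a valid probability and `beta = 1` recovers exact
   independence;
4. c-Fos scoring applies sensitivity `cfosSens` and false-positive rate
   `cfosFpr`; cells are assigned uniformly to 2–3 sections of fixed
   area.

Each animal consumes a private RNG stream seeded from a deterministic
hash of `(seed, animal_id)`, so cohorts are reproducible and animals
independent regardless of simulation order.

### Defaults and what they emulate

The defaults describe a plausible repeated-SD CA1 cohort: 2000 nuclei
per animal, 65% neurons (10% of them inhibitory), SD activating 20% of
excitatory cells against a 3% NSD baseline (activation is therefore
~95% excitatory, matching the observed composition of activated cells),
`tagEff = 0.8`, `bgTag = 0.01` (background labeling is what produces
the small NSD-NSD overlap), `cfosSens = 1`, `cfosFpr = 0.005`, and
`beta = 2`.  These place the overlap-of-tagged percentage near 30% in
SD-SD arms and in the 5–15% range in NSD-NSD arms, the qualitative
regime of the motivating experiments.  No tagging-efficiency or
background-labeling estimates are published for this system, so those
values are conventions chosen once, not fitted quantities; c-Fos
sensitivity defaults to 1 because the marker's short protein half-life
motivates exposing the knob without fixing its value.

```{r defaults}
simConfig()
```

### A caveat that matters: cell-class confounding

With class-heterogeneous activation rates, HA and c-Fos are marginally
**dependent even at `beta = 1`**: excitatory cells are more likely than
astrocytes to be active in *both* epochs, so cell class confounds the
overlap and the random-activation null is false by construction.  This
is a genuine property of the model (and of the real tissue), not a
simulator artifact.  Calibration checks of the null — type-I error of
`cohortRITest()`, consistency of the plug-in bias estimator
`estimateBias()` — therefore use a class-uniform activation
configuration in which every class shares one rate; under it the null
holds exactly at `beta = 1`.  Consequently, a reactivation index above
1 in real tissue is evidence against *class-blind* random activation;
attributing it to within-class reactivation bias requires the
composition analyses of the quantification stage.

### Power analysis

`estimatePower()` simulates SD-SD cohorts, runs each through the full
pipeline (`tabulateOverlap` → `reactivationIndex` → `cohortRITest`) and
reports the rejection fraction with its binomial Monte Carlo standard
error.  With `beta = 1` it measures type-I error; the suite checks it
stays within three standard errors of the nominal 5% over 1000
replicates (5000 cells, 6 animals).  With `beta = 5`, 8 animals and
5000 cells per region, power exceeds 0.9.

## Numerical and degenerate-input choices

* `RI` is undefined when `E = 0` (no tagged or no c-Fos+ cells); such
  animals are flagged `NA` with a logged notice and excluded from the
  cohort test, which requires at least two finite values.  `O > 0` with
  `E = 0` is rejected as impossible (`O ≤ min(K, n)`).
* Zero-variance inputs to any t-test raise an error instructing exact
  reporting instead of fabricating a p-value; zero pooled variance with
  unequal means reports an unbounded t with `p` below machine floor and
  a warning.
* The cohort test runs on raw `RI` against 1 by default, matching the
  published analysis; `logScale = TRUE` tests `log(RI)` against 0 for
  robustness to the right skew of a ratio statistic.
* `N` is the DAPI+ nucleus count of the quantified region.  The model's
  denominator is the total cell population, not the neuronal one, so no
  NeuN-based denominator is offered.
* The hypergeometric tail uses `stats::phyper`; the test suite verifies
  it against full enumeration on every configuration with `N ≤ 12` and
  against a 10⁵-draw label-permutation oracle.
* Validation problem sizes (10⁵ cells for convergence and recovery
  checks, 10³ replicates for calibration) were chosen so Monte Carlo
  standard errors are small relative to the tolerances being checked.

## Limitations

The simulator emulates sampling variability across animals and
sections, detection noise, and the activation/tagging chain; it does
not model spatial structure within a section (beyond uniform section
assignment), tamoxifen pharmacokinetics of the labeling window,
section-to-section staining variability, or correlated segmentation
errors, so passing its checks validates the *statistical* pipeline, not
image processing.  Real per-animal supplementary counts are required to
reproduce published cohort index values exactly; the pipeline consumes
such counts directly via `readOverlapCounts()` when available.
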