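Package: retag
Title: Quantification and Inference for Two-Epoch Activity-Dependent
    Neuronal Tagging Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for repeated sleep-deprivation tagging
    studies of hippocampal ensembles. Converts per-cell marker tables
    (DAPI, NeuN, Sox9, GAD67, HA tag, c-Fos) into area-normalized
    activation densities and cell-type composition fractions, tabulates
    two-epoch label overlap, and tests reactivation against a
    random-activation null via the expected overlap E = n*(K/N), the
    reactivation index RI = O/E, per-animal hypergeometric tail tests and
    a cohort-level one-sample t-test. Includes summary-statistic t-tests,
    Type III two-way ANOVA and Bonferroni adjustment matching standard
    analysis-software conventions, plus a generative simulator of
    two-epoch tagging cohorts with a logistic-odds reactivation bias for
    validation and Monte Carlo power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'conditions.R'
    'AllClasses.R'
    'groupstats.R'
    'io.R'
    'quantify.R'
    'reactivation.R'
    'retag-package.R'
    'simulate.R'
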