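Package: mircombo
Title: Survival-Based Screening of Prognostic miRNA Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of prognostic oncomiR signatures from matched
    expression and clinical follow-up tables: median-split Kaplan-Meier and
    log-rank survival comparison, binary-covariate Cox proportional-hazards
    fits with Efron tie handling, a three-stage screening cascade (single
    oncomiR screen, pairwise synergy detection, exhaustive additive
    combination search over all-high/all-low patient groups), miRNA-target
    inference from expression anti-correlation plus interaction-database
    evidence, and hypergeometric over-representation analysis of the
    resulting target genes.  Includes a synthetic cohort generator with
    planted prognostic miRNAs, synergistic pairs, anti-correlated targets
    and enriched gene sets so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, jsonlite
Suggests: testthat (>= 3.0.0), survival, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
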