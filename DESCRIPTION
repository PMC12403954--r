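Package: zsustain
Title: Subtype and Stage Inference for Brain and Spinal Cord Atrophy Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatiotemporal atrophy subtyping of volumetric
    neuroimaging biomarkers. Implements harmonized z-scoring of brain and
    spinal-cord volumes (batch and covariate adjustment preserving group
    effects, matched-control referencing), a piecewise-linear z-score
    event-based subtype-and-stage model fitted by greedy ascent, EM and
    Metropolis MCMC over constrained event orderings, model selection by
    ten-fold cross-validation information criterion, per-subject subtype and
    probability-weighted stage assignment with a normal-appearing rule,
    longitudinal subtype stability summaries, and clinical characterization
    of subtypes and stages (covariate-adjusted rank tests, contingency
    tests, partial Spearman correlations, Cox proportional-hazards models
    with backward selection, and treatment-response tables). Includes a
    synthetic-cohort generator with known ground-truth subtypes, stages,
    scanner batch structure and stage-linked clinical outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
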