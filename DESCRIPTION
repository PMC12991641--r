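Package: fearrsa
Title: Representational Similarity Analysis of Fear Acquisition, Reversal,
    and Test with Planted Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-phase fear-conditioning fMRI study (acquisition,
    reversal, test in new contexts, test in old contexts) with known item,
    valence-category, and context structure planted in BOLD-like volumes, and
    analyses it end to end: trial-wise least-squares-separate (LSS) beta-series
    estimation, Fisher-z representational similarity metrics (item stability,
    cue generalization, context specificity, item and generalized
    reinstatement), cubic searchlight mapping, nonparametric cluster-level
    family-wise-error inference by sign flipping, and linear mixed-effects
    models linking context specificity to memory reinstatement. Because every
    effect is planted by the generator, each analysis stage is verifiable by
    oracle equivalence and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
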