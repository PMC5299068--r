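Package: dysbiome
Title: Joint Microbiota and NMR Metabolome Analysis of Antibiotic-Induced
    Gut Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for combined 16S fecal-microbiota and
    1H-NMR fecal-metabolome studies of antibiotic perturbation. Provides
    community-ecology statistics on OTU count tables (alpha diversity,
    square-root Bray-Curtis distances, NMDS, PERMANOVA, PERMDISP, SIMPER,
    and a deterministic LDA effect-score variant of LEfSe), NMR spectral
    preprocessing (region exclusion, segment-wise spectral alignment,
    adaptive bucketing with a minimum bin width, probabilistic quotient
    normalization, Pareto scaling), NIPALS-based OPLS-DA with stratified
    double cross-validation, F1-guided component selection and a
    permuted-label reference Q2 distribution, and microbe-metabolite
    integration (volcano tables, SIMPER/FDR feature gating, thresholded
    Spearman correlation matrices with Ward leaf ordering). A synthetic
    study generator with known ground truth emulates a three-group,
    three-timepoint antibiotic challenge design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
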