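Package: plastphen
Title: Plasticity Phenotyping of Synaptic Protein Expression in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying experience-dependent plasticity states of the
    visual cortex from Western-blot measurements of seven glutamatergic and
    GABAergic synaptic proteins (GluN1, GluN2A, GluN2B, GluA2, GABA-A alpha1,
    GABA-A alpha3, synapsin). Implements the full analysis pipeline: gel-control
    and reference normalization, per-condition protein correlation networks with
    Bonferroni-corrected significance and dendrogram seriation, centered-SVD
    principal component analysis with cos2 diagnostics, construction and
    screening of nine plasticity features (three scaled protein sums and six
    contrast indices), tSNE embedding with k-means clustering and an
    exponential-tau elbow rule, color-coded plasticity phenotype bands with a
    bootstrap Monte-Carlo comparison against a normal reference, and a
    population decay-kinetics model for NMDA and GABA-A receptor subunit mixes.
    A synthetic-data generator emulates the study design (rearing conditions,
    cortical regions, replicate runs, planted condition effects) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rtsne,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    ggplot2,
    mclust,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
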