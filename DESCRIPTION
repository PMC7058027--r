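Package: astromap
Title: Astrocyte Subtype Quantification from Single-Cell RNA-seq, Multiplexed
    ISH and Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipelines for studies of astrocyte heterogeneity
    in the adult mouse cortex and hippocampus. Implements single-cell
    count-matrix quality control, ln-normalization, highly-variable-gene
    selection with explicit mean/dispersion thresholds, silhouette-selected
    hierarchical clustering, higher-order cell typing and marker-gene calling
    (fold-change, percent-expressing and rank-sum criteria); rule-based
    mapping of astrocyte subtypes from multiplexed in situ hybridization
    puncta counts, including regional distributions and fluorescence-threshold
    robustness sweeps; and calcium transient detection and parameterization
    (dF/F0, peak amplitude, prominence, width at half prominence, frequency,
    area under the curve) with responder filtering, physiology clustering and
    nonparametric group comparisons. A synthetic-data generator with planted
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
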