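Package: qtlMeta
Title: Meta-Analysis of Quantitative Trait Loci on Consensus Genetic Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-QTL analysis of literature-curated quantitative
    trait locus (QTL) compendia, developed around maize plant-height and
    ear-height studies but applicable to any diploid linkage-map species.
    Provides quality control and Darvasi-Soller confidence-interval
    imputation for multi-study QTL tables, homothetic projection of QTLs
    onto a reference (consensus) genetic map through flanking common
    markers, per-chromosome Gaussian meta-analysis with exact
    dynamic-programming clustering and five-criterion (AIC, AICc, AIC3,
    BIC, AWE) model-selection voting, inverse-variance estimation of
    meta-QTL positions and confidence intervals, genetic-to-physical
    coordinate interpolation with candidate-gene extraction from GFF3
    annotations, and a fully deterministic synthetic-compendium generator
    with ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, QualityControl, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'compendium.R'
    'fixtures.R'
    'map_projection.R'
    'meta_analysis.R'
    'physical_anchoring.R'
    'qtlMeta-package.R'
    'synthetic_data.R'
    'utils.R'
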