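Package: topomicro
Title: Topographic Habitat Association and Co-Occurrence Analysis for Soil
    Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses quadrat-by-OTU amplicon count tables sampled on a
    gridded forest plot spanning topographic habitats (valley, mid-slope,
    ridge). Classifies each OTU as positively, negatively or neutrally
    associated with each habitat using a torus-translation randomization
    that preserves spatial autocorrelation; infers compositionality-aware
    co-occurrence networks with the SparCC estimator, permutation edge
    significance and Louvain module detection; quantifies community
    structure (richness contrasts, shared/unique OTU partitions,
    Bray-Curtis/NMDS ordination, rarefaction, ternary enrichment) and
    environmental drivers (permutational vector fitting, redundancy
    analysis). Includes a Dirichlet-multinomial simulator of gridded plots
    with known habitat specialists so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
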