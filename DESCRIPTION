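Package: halovir
Title: Viral Community Analysis for Hypersaline Estuary Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing viral metagenome (virome) time series from
    hypersaline estuaries sampled under pulse disturbances such as freshwater
    inundation and freeze events. Implements ensemble viral-contig consensus
    calling, dereplication of viral contigs into viral operational taxonomic
    units (vOTUs) at 95% average nucleotide identity and 85% aligned fraction,
    coverage-breadth detection filtering with length- and depth-normalised
    abundances, gene-level majority-rule taxonomy and source-environment
    assignment, permutation-based community statistics (ANOSIM, PERMANOVA,
    environmental vector fitting, best-subset environmental correlation,
    non-metric multidimensional scaling on centred log-ratio distances),
    k-medoid clustering of temporal abundance profiles with elbow and
    silhouette model selection, and filtering of virus-host predictions into
    an order-level bipartite network. A synthetic-data generator reproduces
    the two-site, eight-timepoint disturbance design with known ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    cluster,
    stats,
    utils,
    methods
Suggests:
    vegan,
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
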