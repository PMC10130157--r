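Package: culturebench
Title: Multi-Dimensional Evaluation of Ex Vivo Gut-Microbiome Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring how faithfully ex vivo fecal cultures
    reproduce the donor's in situ gut microbiome. Implements taxonomic
    aggregation and alpha-diversity (Shannon, Gini-Simpson), culture-to-feces
    dissimilarity (Jensen-Shannon divergence, Euclidean, Bray-Curtis),
    multi-factor PERMANOVA with sequential sums of squares and permutation
    p-values, enterotype clustering (partitioning around medoids on
    Jensen-Shannon distances), a composite medium ranking that averages
    per-metric ranks with metric-specific directions, qPCR and optical-density
    growth metrics, and calibration-based quantification of microbial drug
    metabolism from LC-MS peak-area ratios. A synthetic-data generator with
    donor, medium and time effects makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
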