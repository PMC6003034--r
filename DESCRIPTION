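Package: arganet
Title: Quality Indices, Fatty-Acid Profiles and Partial-Correlation
    Networks for Argan Oil Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the chemometric characterisation of argan (Argania
    spinosa) oils: physicochemical quality indices from titration and
    absorbance readings (free acidity, acid index, polyphenol, chlorophyll
    and carotenoid contents, quality-grade classification), fatty-acid
    profile normalisation from GC peak areas with the derived nutritional
    indices (total SFA/UFA, P/S index, UFA/SFA ratio), pairwise Pearson
    correlation screening with two-sided p-values, and a Gaussian
    graphical-model network built from a shrinkage precision matrix with a
    partial-variance orientation heuristic that yields a directed acyclic
    graph over composition and provenance variables. Includes seeded
    generators for linear-Gaussian structural equation data and synthetic
    oil cohorts so every pipeline stage is testable at desk scale, and
    exporters to Graphviz DOT, GraphML and adjacency CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
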