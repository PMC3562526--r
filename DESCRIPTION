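Package: xspecies
Title: Cross-Species Microarray Analysis with Genomic DNA Probe Masking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for heterologous (cross-species) microarray
    hybridizations: genomic-DNA-based probe masking with threshold
    optimization, mask-aware RMA summarization (background correction,
    quantile normalization, median polish), two-group differential
    expression with Benjamini-Hochberg correction, chord-distance
    complete-linkage clustering, Wilcoxon functional-bin enrichment,
    relative-standard-curve qPCR quantification, and neighbor-joining
    trees from aligned protein sequences. Includes a synthetic
    cross-species hybridization simulator with known probe divergence and
    planted differential expression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
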