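Package: regulogr
Title: Conservation of Transcription-Factor Types in Reduced Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcriptional regulatory networks of reduced
    bacterial genomes from a reference network by the regulog approach
    (bidirectional best-hit orthology with e-value, identity and coverage
    thresholds), tests for preferential conservation of activators,
    repressors and dual regulators with one-sided hypergeometric tests
    combined across genomes by Fisher's method, scores global regulators
    with a four-component connectivity metric, corrects cross-genome
    correlations for phylogeny with Felsenstein's independent contrasts
    (positivized, through-origin statistics), and relates TF-type fractions
    to genome size, global-regulator content and nucleoid-associated
    proteins via standardized multivariate regression. A synthetic
    genome-reduction generator (Yule trees, lineage-heterogeneous gene-loss
    hazards per TF type, BLAST-tabular hit tables) makes the whole pipeline
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
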