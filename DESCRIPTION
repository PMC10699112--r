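Package: meiocascade
Title: Master-Regulator Cascades and Purifying Selection in Yeast Meiosis
Version: 0.1.0
Authors@R:
    person("Meiocascade", "Developers", email = "meiocascade@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for identifying master regulators of
    meiosis initiation and commitment in budding yeast from
    differential expression, protein-interaction and gene-regulatory
    networks under a hierarchy-index statistic, and for quantifying
    purifying selection on the resulting transcriptional cascades with
    Nei-Gojobori (1986) dN/dS estimates, a codon-based Z-test,
    generalized-ESD outlier removal and Mann-Whitney phase comparison.
    Includes a synthetic-data generator with planted ground truth so
    every stage carries parameter-recovery tests without any external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
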