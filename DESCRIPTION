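Package: equimir
Title: Small RNA-Seq MicroRNA Discovery and Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a small RNA-seq microRNA
    discovery workflow for animal genomes: adapter trimming and read
    cleaning, collapsing of inserts to unique tags, exact-match genome
    mapping, catalog-based tag annotation with a fixed category priority,
    hairpin folding and ten-criteria novel miRNA calling (length, read
    depth at the cut site, copy number, free energy, duplex geometry and
    flanks), 3-kb polycistron clustering, and nucleotide-composition
    profiling. Ships a synthetic-data generator that plants ground-truth
    miRNA hairpins and single-criterion decoy loci in a toy genome so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
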