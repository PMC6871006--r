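Package: uvigkit
Title: Quality Assessment, Metadata Validation and vOTU Clustering for
    Uncultivated Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools implementing community reporting standards for
    uncultivated virus genomes (UViGs): validation of MIUViG-style
    metadata records against the checklist of mandatory fields and
    controlled vocabularies; detection of direct and inverted terminal
    repeats as sequence-level evidence of genome completeness;
    reference-length based completeness estimation and assignment of the
    three assembly-quality tiers (genome fragment, high-quality draft,
    finished); window-based average nucleotide identity (ANI) and
    alignment fraction (AF) computation with species-rank clustering of
    genomes into virus operational taxonomic units (vOTUs); and a
    synthetic genome generator with known ground truth for benchmarking,
    including a fragmentation-bias experiment for whole-genome ANI
    estimated from partial assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
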