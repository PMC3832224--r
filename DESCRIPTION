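Package: streamscan
Title: Streamlining Metrics, Fragment Recruitment and Proteome Acidity
    Profiles for Halophile Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for streamlined halophilic
    prokaryotes. Computes genome streamlining metrics (GC content, coding
    density, intergenic-spacer distributions), fragment-based average
    nucleotide identity (ANI), metagenomic fragment recruitment with
    size-normalised abundance, genomic-island calling from recruitment
    coverage profiles, and whole-proteome isoelectric-point ("virtual
    2D-gel") profiles. Includes a deterministic synthetic-community
    generator (genomes, diverged lineages, flexible genomic islands,
    error-bearing reads, style-controlled proteomes) so every analysis can
    be exercised against known truth, and a pipeline driver that runs all
    stages from a single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
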