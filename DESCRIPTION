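Package: phagechar
Title: Phenotypic and Genomic Characterization of Lytic Bacteriophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of lytic bacteriophages from bench
    assay time series and genome sequence. Implements killing-curve local
    virulence and the integrated virulence index, one-step-growth latent
    period and burst size estimation, adsorption kinetics, crystal-violet
    biofilm inhibition and stability log-reductions; a scanner for -1
    programmed ribosomal frameshift (PRF) signals at tail assembly chaperone
    loci built on a deterministic global and center-star aligner;
    whole-genome statistics (GC content, direct terminal repeat borders, ORF
    extraction); a Fisher/Benjamini-Hochberg enrichment screen for
    defense-system presence/absence tables; and seeded synthetic-data
    generators with known ground truth for every assay, so the full analysis
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    pracma,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
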