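Package: markerscreen
Title: Marker-Gene Screening and Quantification in Shotgun Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens shotgun metagenome and metatranscriptome reads for a
    marker protein family (for example the anaerobic gamma-butyrobetaine
    reductase gene bbuA of the gut bbu cluster) using translated six-frame
    search against a marker database together with a competitive
    negative-control (decoy) database of near-neighbour homologs.
    Provides marker/decoy database construction with greedy identity
    clustering, Smith-Waterman local alignment with k-mer seeding,
    RPKM and average-genome-size normalisation to genes per microbial
    genome, cohort-level prevalence, gene/transcript concordance and
    nonparametric metabolite-association statistics, plus a synthetic
    community, read and cohort simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
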