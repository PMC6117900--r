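Package: metabarcoder
Title: Multilocus Metabarcode Construction and Metagenomic Read Binning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects concatenated multilocus "metabarcode" reference sequences
    from sets of annotated bacterial genomes and uses them to detect those
    genomes in shotgun metagenomic read sets. Orthologous gene clusters are
    built by reciprocal best hits, partitioned into core and accessory
    genome, codon-aligned and ranked by a divergence-based suitability score;
    top-ranking genes are concatenated into per-genome barcodes. Reads are
    aligned to the barcodes with a seeded local aligner, filtered by an
    adaptive score threshold, corrected for read- and alignment-level
    specificity and for the taxonomic vicinity of multiply-hit barcodes, and
    aggregated into per-barcode detection scores compared against cut-offs.
    Includes a genome-family and metagenome simulator with known truth and
    ROC/confusion evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
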