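Package: hgcscan
Title: Detection and Quantification of Mercury-Methylation Marker Genes in
    Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for detecting and quantifying the mercury
    methylation marker genes hgcA and hgcB in shotgun metagenomic read sets.
    Provides paired-end adapter trimming, overlap merging and quality
    filtering; six-frame open-reading-frame prediction under the bacterial
    genetic code; position-specific profile models built from reference
    protein alignments with Gumbel-calibrated E-values; conserved-motif
    validation of candidate hits (cap-helix cysteine for HgcA, duplicated
    CX2CX2CX3C ferredoxin motifs for HgcB); normalization of marker counts to
    the single-copy gene recA; KEGG-style module completion ratios from KO
    abundance tables; and rank correlation of marker abundance against total
    mercury and methylmercury depth profiles with detection-limit censoring.
    A synthetic-data module generates reference families, spiked communities,
    paired-end reads, KO tables and mercury chemistry tables with known
    ground truth so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
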