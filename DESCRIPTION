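Package: ucetools
Title: Identification, Bait Design, Harvesting and Analysis of Ultraconserved Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for target-enrichment phylogenomics built on
    ultraconserved elements (UCEs). Detects perfectly conserved regions in MAF
    whole-genome alignments, screens duplicate-like loci, buffers loci and tiles
    120-nt enrichment baits with repeat/GC/ambiguity filters, matches assembled
    contigs back to loci with identity and coverage thresholds, assembles
    completeness-filtered phylogenomic supermatrices with per-locus character
    sets and parsimony-informative-site counts, computes qPCR fold-enrichment
    summaries, and ranks and model-averages generalized linear models of
    capture success by Akaike weight. Includes a deterministic synthetic-data
    generator that plants conserved elements, duplicates, soft-masked repeats,
    diverged contigs and crossing-point tables with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
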