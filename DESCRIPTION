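Package: guidecraft
Title: Guide RNA Design with On-Target Scoring and Annotated Off-Target Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of CRISPR/Cas9 single guide RNAs from arbitrary query
    sequences and custom genomes. Enumerates all 20-mer protospacers matching a
    configurable PAM (IUPAC, up to 6 bp) on both strands, reports per-guide
    sequence features (GC content excluding the PAM, homopolymer runs,
    4-nt self-complementarity against the guide and the sgRNA backbone),
    scores on-target efficiency with a trainable gradient-boosted regression
    model over the Rule Set 2 feature scheme (position-dependent nucleotides,
    nucleotide counts, GC features, PAM-bookend dinucleotide, nearest-neighbor
    melting temperatures), scans unindexed genomes for off-target loci within
    four mismatches under PAM-compatibility rules, scores hits with the
    multiplicative CFD scheme, and annotates them against a GTF. Includes a
    synthetic fixture generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
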