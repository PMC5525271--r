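Package: deetiolR
Title: Small RNA and Degradome Analysis for De-Etiolating Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of small regulatory RNAs (miRNAs, siRNAs, phasiRNAs) and
    degradome (PARE) libraries across a dark-to-light seedling time course.
    Detects phased-siRNA (PHAS/TAS) loci with a hypergeometric phasing
    statistic over 21-nt registers in sliding windows, calls sRNA-guided
    mRNA cleavage events from degradome 5' end profiles (complementarity
    scoring, rank-based site categories, dinucleotide-shuffle empirical
    p-values, validity filtering, T-plot export), quantifies sRNA expression
    with family-weighted counting and reads-per-million normalization,
    classifies expressed and light-regulated sRNAs, and provides the
    comparative statistics of sRNA-to-target determinant analysis
    (Kolmogorov-Smirnov tests, fold-change t-tests, Fisher enrichment,
    k-means clustering of light-response profiles). A fully specified
    synthetic-data generator with ground-truth tables makes every pipeline
    stage testable without external sequencing libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
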