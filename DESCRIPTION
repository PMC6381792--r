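Package: linkLD
Title: Joint Linkage and Linkage-Disequilibrium Mapping of Dynamic Growth Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for joint linkage and linkage-disequilibrium (association)
    mapping of longitudinal quantitative traits in forest trees. Implements
    Haley-Knott interval mapping with permutation thresholds and multiple-QTL
    cofactor rescans on pseudo-testcross full-sib families, QTL hotspot
    permutation tests, projection of QTL support intervals onto genomic
    coordinates via anchor markers, windowed population-genetic selection
    scans (nucleotide diversity, Watterson's theta, Tajima's D,
    Weir-Cockerham Fst, reduction of diversity), linkage-disequilibrium
    structure (pairwise r2, high-LD blocks, Hill-Weir decay fits),
    mixed-linear-model association with additive/dominance decomposition, and
    two-locus Kempthorne-style epistasis partitioning. Ships simulators for
    structured association panels (Balding-Nichols) and full-sib linkage
    populations with planted causal loci so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    rtracklayer,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
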