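Package: scramblr
Title: Collinearity Segmentation and Genome Scrambling Statistics for
    Pairwise Whole-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies genome scrambling between pairs of chromosome-scale
    genome assemblies from one-to-one whole-genome alignments.  Reads PAF and
    two-species MAF alignments, GFF3 gene models and ortholog tables; chains
    alignments under a strict collinearity definition and partitions the
    target genome into collinear alignments, bridge regions, breakpoint
    regions and isolated alignments; computes the strand-randomisation
    (scrambling) index, breakpoint accumulation rates, ortholog-based
    macrosynteny blocks, operon calling and cross-genome operon conservation,
    boundary feature-enrichment profiles and percent-length chromosome
    profiles with arm-class comparisons.  Includes a coordinate-level genome
    rearrangement simulator that evolves an annotated ancestral genome by
    logged inversions, translocations, deletions and duplications, providing
    ground truth for every downstream statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
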