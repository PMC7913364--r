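Package: lrpanel
Title: Long-Range PCR Amplicon Panel Sequencing Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational support for long-range (LR) PCR amplicon panel
    sequencing workflows used in Mendelian diagnostics. Provides amplicon-panel
    accounting (target sizes, coverage gaps, amplicon overlaps, allele-dropout
    risk), deterministic pooling and library stoichiometry calculators
    (dilutions, size-proportional amplicon pooling, molarity, target-size
    proportional index pooling, exome spike-in amounts), read-backed cis/trans
    phasing of candidate compound-heterozygous variants via a fragment parity
    graph, microhomology-aware deletion breakpoint characterization with
    ambiguous-interval HGVS g. reporting, per-base depth QC, and a seeded
    simulator that generates toy references, two-haplotype read sets, and
    deletion-bearing amplicons for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    BiocGenerics,
    IRanges,
    Biostrings,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
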