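Package: mitosurvey
Title: Population Survey of Mitochondrial DNA Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for surveying single-nucleotide polymorphism in aligned
    complete mitochondrial genomes from two populations of unequal size.
    Identifies polymorphic sites and minor alleles, classifies them as
    synonymous (including four-fold degenerate), nonsynonymous, tRNA, rRNA or
    other non-coding, attaches externally supplied effect (benign/damaging)
    and pathogenic-catalogue annotations, and summarises each category by
    variable-site counts, mean minor-allele frequency and per-genome burden.
    Nucleotide diversity is partitioned into synonymous and nonsynonymous
    components with the Nei-Gojobori (1986) method under the vertebrate
    mitochondrial genetic code, with pairwise deletion of missing data.
    Unequal sample sizes are handled by seeded Monte-Carlo subsampling and
    group contrasts use Mann-Whitney U-tests. A synthetic-data module
    generates complete, self-consistent input bundles with planted
    per-category allele-frequency structure so that every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
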