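Package: malines
Title: Genome Instability Analysis for Mutation Accumulation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of whole-genome sequencing data from mutation
    accumulation (MA) experiments in hybrid diploid yeast. Classifies five
    classes of genomic variation events (single-nucleotide variants, small
    insertions/deletions, loss of heterozygosity, chromosomal rearrangements,
    and aneuploidy) from per-isolate variant tables, heterozygous marker
    genotypes, and normalized read-depth tracks; estimates per-division and
    per-base-pair mutation rates; tests loss-of-heterozygosity enrichment at
    genomic elements (centromeres, G-quadruplex motifs, GC-content classes)
    with a length-fraction expected-count chi-square statistic; quantifies
    APOBEC3B-signature strand bias across replication-origin intervals; and
    detects hypermutator lineages. Includes a synthetic-data generator that
    emulates hybrid-diploid MA sequencing so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    graphics,
    stats,
    utils,
    tools,
    IRanges,
    Biostrings,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
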