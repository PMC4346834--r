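Package: immunexpand
Title: Comparative Immunogenomics of Expanded Innate-Immune Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative immunogenomics workflow
    for expanded innate-immune gene families in a bivalve genome: assembly of an
    immune-gene catalog from multiple evidence sets with a read-depth filter
    against haplotype-inflated allelic duplicates, rule-based classification of
    Toll-like receptor domain architectures into five subtypes, exact
    differential-expression tests for replicate-free pooled RNA-seq libraries
    with response-class and specificity classification, tandem-array and
    lineage-specific-expansion detection with neighbor-joining trees and
    bootstrap supports, counting-based dN/dS estimation with a per-site
    positive-selection scan, and phylostratigraphic gene-age assignment over ten
    ranked taxonomic levels. All inputs can be simulated with planted ground
    truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
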