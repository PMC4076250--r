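Package: longscaff
Title: Scaffolding Draft Genome Assemblies with Uncorrected Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients pre-assembled draft contigs into scaffolds
    using uncorrected single-molecule long reads (e.g. PacBio CLR) as a
    backbone. Local read-to-contig alignments (PAF or BLASR m4) are filtered
    to the best non-overlapping placements per read, per-read placement
    order is converted into an oriented contig-linkage graph with transitive
    reduction and repeat detection, and contigs are chained into scaffolds
    with repeat placement, gap-size estimation and overlap merging. Includes
    a CLR-style read and genome simulator with ground-truth bookkeeping and
    a truth-based scaffold evaluator, plus FASTA, AGP v2.1 and summary
    output for downstream submission pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
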