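Package: varstore
Title: Local Variant Warehouse with Group-Based Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A local, self-contained warehouse for SNP and indel calls from
    multi-sample resequencing projects. Per-sample call tables are combined
    with denormalized, indexed summary tables that track the carrier-sample
    set and functional annotation of every distinct variant, so that
    group-based filtering (in-/discard-/filter-group partitions with
    carrier-frequency thresholds, functional-class constraints and dbSNP
    exclusion) runs at a cost independent of cohort size. Includes an
    import-time functional annotator (gene-model region classes, coding
    effects via the standard genetic code, dbSNP and score lookups), a
    naive join-and-loop filter used as a correctness and scaling baseline,
    a synthetic-cohort generator with planted Mendelian and
    population-specific truths, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
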