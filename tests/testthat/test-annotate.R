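# A small hand-built gene set used across the region tests:
#   PLUSG  (+) two exons, coding
#   MINUSG (-) single exon, coding
#   NCG        non-coding single exon
#   OVLA/OVLB  overlapping genes: position in OVLA's intron but OVLB's exon
toy_models <- function() {
  data.table::rbindlist(list(
    data.table::data.table(
      gene_symbol = "PLUSG", transcript_id = "PLUSG-t1", chrom = "chr1",
      strand = "+", tx_start = 1000L, tx_end = 2000L,
      cds_start = 1050L, cds_end = 1950L,
      exon_starts = list(c(1000L, 1500L)), exon_ends = list(c(1100L, 2000L)),
      cds_seq = NA_character_),
    data.table::data.table(
      gene_symbol = "MINUSG", transcript_id = "MINUSG-t1", chrom = "chr1",
      strand = "-", tx_start = 5000L, tx_end = 5099L,
      cds_start = 5010L, cds_end = 5090L,
      exon_starts = list(5000L), exon_ends = list(5099L),
      cds_seq = NA_character_),
    data.table::data.table(
      gene_symbol = "NCG", transcript_id = "NCG-t1", chrom = "chr2",
      strand = "+", tx_start = 100L, tx_end = 400L,
      cds_start = NA_integer_, cds_end = NA_integer_,
      exon_starts = list(c(100L, 300L)), exon_ends = list(c(200L, 400L)),
      cds_seq = NA_character_),
    data.table::data.table(
      gene_symbol = "OVLA", transcript_id = "OVLA-t1", chrom = "chr3",
      strand = "+", tx_start = 1000L, tx_end = 3000L,
      cds_start = 1010L, cds_end = 2990L,
      exon_starts = list(c(1000L, 2500L)), exon_ends = list(c(1200L, 3000L)),
      cds_seq = NA_character_),
    data.table::data.table(
      gene_symbol = "OVLB", transcript_id = "OVLB-t1", chrom = "chr3",
      strand = "+", tx_start = 1900L, tx_end = 2300L,
      cds_start = 1910L, cds_end = 2290L,
      exon_starts = list(1900L), exon_ends = list(2300L),
      cds_seq = NA_character_)))
}

test_that("region classification follows the precedence rules", {
  models <- toy_models()
  # inside the CDS of an exon
  r <- classify_region("chr1", 1060, models)
  expect_equal(r$region_class, "exonic")
  expect_equal(r$gene_symbol, "PLUSG")
  # 1 bp and 2 bp into the intron beside a junction -> splicing; 3 bp -> intronic
  expect_equal(classify_region("chr1", 1101, models)$region_class, "splicing")
  expect_equal(classify_region("chr1", 1102, models)$region_class, "splicing")
  expect_equal(classify_region("chr1", 1103, models)$region_class, "intronic")
  expect_equal(classify_region("chr1", 1499, models)$region_class, "splicing")
  # splice_window = 0 turns those into plain intronic
  expect_equal(classify_region("chr1", 1101, models, splice_window = 0)$region_class,
               "intronic")
  # UTRs respect strand: below cds_start is UTR5 on +, UTR3 on -
  expect_equal(classify_region("chr1", 1010, models)$region_class, "UTR5")
  expect_equal(classify_region("chr1", 1990, models)$region_class, "UTR3")
  expect_equal(classify_region("chr1", 5005, models)$region_class, "UTR3")
  expect_equal(classify_region("chr1", 5095, models)$region_class, "UTR5")
  # upstream/downstream within 1 kb, strand-aware
  expect_equal(classify_region("chr1", 999, models)$region_class, "upstream")
  expect_equal(classify_region("chr1", 2500, models)$region_class, "downstream")
  expect_equal(classify_region("chr1", 5100, models)$region_class, "upstream")
  # non-coding transcript
  expect_equal(classify_region("chr2", 150, models)$region_class, "ncRNA")
  expect_equal(classify_region("chr2", 250, models)$region_class, "ncRNA")
  # no hit anywhere
  r <- classify_region("chr9", 1, models)
  expect_equal(r$region_class, "intergenic")
  expect_equal(r$gene_symbol, "")
  # overlapping genes: intron of OVLA but exon of OVLB -> exonic, OVLB
  r <- classify_region("chr3", 2000, models)
  expect_equal(r$region_class, "exonic")
  expect_equal(r$gene_symbol, "OVLB")
})

test_that("region classification matches the per-base brute-force scan", {
  set.seed(11)
  d <- withr::local_tempdir()
  for (rep in 1:4) {
    fx <- generate_gene_fixture(file.path(d, paste0("fx", rep)),
                                seed = 100 + rep, n_genes = 5)
    models <- fx$models
    span <- range(models$tx_start, models$tx_end)
    pos <- sample(seq(span[1] - 1500L, span[2] + 1500L), 300L)
    for (p in pos) {
      got <- classify_region("chrT", p, models)
      want <- brute_classify_region("chrT", p, models)
      expect_identical(got$region_class, want$region_class)
    }
  }
})

test_that("coding effects follow the standard genetic code", {
  m <- data.table::data.table(
    gene_symbol = "G", transcript_id = "T", chrom = "chr1", strand = "+",
    tx_start = 101L, tx_end = 109L, cds_start = 101L, cds_end = 109L,
    exon_starts = list(101L), exon_ends = list(109L), cds_seq = "ATGGCTTAA")
  v <- function(pos, ref, alt) list(chrom = "chr1", pos = pos, ref = ref,
                                    alt = alt)
  # codon 2 GCT(Ala): middle base C>T -> GTT(Val), nonsynonymous
  r <- classify_coding_effect(v(105, "C", "T"), m)
  expect_equal(r$effect_class, "nonsynonymous")
  expect_equal(r$context$codon_ref, "GCT")
  expect_equal(r$context$codon_alt, "GTT")
  expect_equal(r$context$aa_ref, "A")
  expect_equal(r$context$aa_alt, "V")
  # third base T>A -> GCA, still Ala: synonymous
  expect_equal(classify_coding_effect(v(106, "T", "A"), m)$effect_class,
               "synonymous")
  # stop codon TAA -> CAA: stoploss; and TAC codon gaining a stop
  expect_equal(classify_coding_effect(v(107, "T", "C"), m)$effect_class,
               "stoploss")
  m2 <- data.table::copy(m)
  m2$cds_seq <- "ATGTACTAA"
  expect_equal(classify_coding_effect(v(106, "C", "A"), m2)$effect_class,
               "stopgain")
  # outside the CDS is a contract violation
  expect_error(classify_coding_effect(v(200, "A", "G"), m), "outside the CDS")
  # disagreement with the CDS sequence is refused
  expect_error(classify_coding_effect(v(105, "G", "T"), m), "disagrees")

  # all 9 substitutions of each toy codon agree with an independent
  # translation (seqinr) of the mutated codon
  for (codon_seq in c("ATGGCTTAA", "ATGTGGTAA", "ATGTACTAA")) {
    mc <- data.table::copy(m)
    mc$cds_seq <- codon_seq
    codon <- substr(codon_seq, 4, 6)
    for (within in 0:2) {
      refb <- substr(codon, within + 1, within + 1)
      for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
        got <- classify_coding_effect(v(104L + within, refb, altb), mc)
        mut <- codon
        substr(mut, within + 1, within + 1) <- altb
        aa_ref <- seqinr::translate(strsplit(codon, "")[[1]])
        aa_alt <- seqinr::translate(strsplit(mut, "")[[1]])
        want <- if (aa_ref == aa_alt) "synonymous"
                else if (aa_alt == "*") "stopgain"
                else if (aa_ref == "*") "stoploss"
                else "nonsynonymous"
        expect_equal(got$effect_class, want)
      }
    }
  }
})

test_that("indel coding effects are decided by length mod 3", {
  v <- function(ref, alt) list(chrom = "chr1", pos = 105L, ref = ref, alt = alt)
  for (len in 1:6) {
    del <- classify_coding_effect(v(strrep("A", len), "-"), NULL, NA)
    ins <- classify_coding_effect(v("-", strrep("A", len)), NULL, NA)
    want <- if (len %% 3 == 0) "nonframeshift" else "frameshift"
    expect_equal(del$effect_class, want)
    expect_equal(ins$effect_class, want)
  }
  # balanced multi-base substitution does not shift the frame
  expect_equal(classify_coding_effect(v("AC", "GT"), NULL, NA)$effect_class,
               "nonframeshift")
})

test_that("a gene and its reverse-complement mirror give identical effects", {
  # plus-strand gene at [101,109]; mirror gene on the minus strand with the
  # same coding sequence. Genomic offset o on the plus gene corresponds to
  # genomic offset 8-o on the mirror, with complemented alleles.
  cds <- "ATGGCTTAA"
  plus <- data.table::data.table(
    gene_symbol = "FWD", transcript_id = "FWD-t1", chrom = "chr1",
    strand = "+", tx_start = 101L, tx_end = 109L, cds_start = 101L,
    cds_end = 109L, exon_starts = list(101L), exon_ends = list(109L),
    cds_seq = cds)
  minus <- data.table::data.table(
    gene_symbol = "REV", transcript_id = "REV-t1", chrom = "chr2",
    strand = "-", tx_start = 201L, tx_end = 209L, cds_start = 201L,
    cds_end = 209L, exon_starts = list(201L), exon_ends = list(209L),
    cds_seq = cds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (o in 0:8) {
    refb <- substr(cds, o + 1, o + 1)
    for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
      fwd <- classify_coding_effect(
        list(chrom = "chr1", pos = 101L + o, ref = refb, alt = altb), plus)
      rev <- classify_coding_effect(
        list(chrom = "chr2", pos = 209L - o, ref = comp[[refb]],
             alt = comp[[altb]]), minus)
      expect_equal(rev$effect_class, fwd$effect_class)
      expect_equal(rev$context$codon_alt, fwd$context$codon_alt)
    }
  }
})

test_that("dbSNP and score lookups match on the full variant key", {
  d <- withr::local_tempdir()
  db_path <- file.path(d, "dbsnp.tsv")
  writeLines(c("chrom\tpos\tref\talt\trsid\tcommon_flag",
               "chr2\t69049697\tC\tT\trs199643431\tFALSE",
               "chr7\t100\tA\tG\trs1\tTRUE"), db_path)
  db <- read_dbsnp_table(db_path)
  hit <- lookup_dbsnp(list(chrom = "chr2", pos = 69049697, ref = "C",
                           alt = "T"), db)
  expect_equal(hit$rsid, "rs199643431")
  expect_false(hit$is_dbsnp_common)
  # absent key, and same position with a different alt allele
  expect_equal(lookup_dbsnp(list(chrom = "chr2", pos = 70439862, ref = "C",
                                 alt = "T"), db)$rsid, "")
  expect_equal(lookup_dbsnp(list(chrom = "chr2", pos = 69049697, ref = "C",
                                 alt = "G"), db)$rsid, "")
  expect_true(lookup_dbsnp(list(chrom = "chr7", pos = 100, ref = "A",
                                alt = "G"), db)$is_dbsnp_common)

  sc_path <- file.path(d, "scores.tsv")
  writeLines(c("chrom\tpos\tref\talt\tSIFT\tPolyPhen2\tGERP",
               "chr2\t69049697\tC\tT\t0.01\t\t4.1"), sc_path)
  sc <- read_score_table(sc_path)
  got <- lookup_scores(list(chrom = "chr2", pos = 69049697, ref = "C",
                            alt = "T"), sc)
  expect_equal(got[["SIFT"]], 0.01)
  expect_equal(got[["GERP"]], 4.1)
  expect_false("PolyPhen2" %in% names(got))   # empty cell omitted
  expect_length(lookup_scores(list(chrom = "chr2", pos = 1, ref = "A",
                                   alt = "G"), sc), 0)
  # indel keys get an empty map: the score catalogue covers SNVs only
  expect_length(lookup_scores(list(chrom = "chr2", pos = 69049697, ref = "-",
                                   alt = "T"), sc), 0)
})

test_that("annotate_variant composes region, effect and lookups deterministically", {
  d <- withr::local_tempdir()
  fx <- build_wdm_fixture(file.path(d, "wdm"))
  annodb <- annotation_db(
    gene_models = file.path(fx$store$path, "annotation", "gene_models.tsv"),
    dbsnp = file.path(fx$store$path, "annotation", "dbsnp.tsv"),
    scores = file.path(fx$store$path, "annotation", "scores.tsv"))
  tia1 <- list(chrom = "chr2", pos = 70439862, ref = "C", alt = "T")
  a <- annotate_variant(tia1, annodb)
  expect_equal(a$region_class, "exonic")
  expect_equal(a$effect_class, "nonsynonymous")
  expect_equal(a$gene_symbol, "TIA1")
  expect_equal(a$rsid, "")
  expect_false(a$is_dbsnp_common)
  expect_equal(a$scores[["SIFT"]], 0.01)
  # identical inputs, identical results
  expect_identical(a, annotate_variant(tia1, annodb))
  # intergenic SNV with an rsid
  b <- annotate_variant(list(chrom = "chr4", pos = 5000000, ref = "A",
                             alt = "G"), annodb)
  expect_equal(b$region_class, "intergenic")
  expect_equal(b$effect_class, "none")
  expect_equal(b$rsid, "rs99000001")
  expect_true(b$is_dbsnp_common)
  # exonic 1-bp deletion is a frameshift in its gene
  del <- annotate_variant(list(chrom = "chr2", pos = 70439862, ref = "C",
                               alt = "-"), annodb)
  expect_equal(del$region_class, "exonic")
  expect_equal(del$effect_class, "frameshift")
})

test_that("every variant gets exactly one region class and tallies partition", {
  d <- withr::local_tempdir()
  fx <- generate_gene_fixture(file.path(d, "fx"), seed = 3, n_genes = 4)
  annodb <- annotation_db(gene_models = fx$gene_models)
  set.seed(4)
  pos <- sample(seq(50000L, 500000L), 200L)
  classes <- vapply(pos, function(p) {
    annotate_variant(list(chrom = "chrT", pos = p, ref = "A", alt = "G"),
                     annodb)$region_class
  }, "")
  expect_true(all(classes %in% c("exonic", "splicing", "ncRNA", "UTR5",
                                 "UTR3", "intronic", "upstream", "downstream",
                                 "intergenic")))
  expect_length(classes, 200L)
})
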