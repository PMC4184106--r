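## The worked-example fixture: a store reproducing, at desk scale, the
## published candidate screen for Welander Distal Myopathy — two affected,
## unrelated exomes in the in-group, everything else in the filter-group,
## at most one filter-group carrier allowed. The 13 candidate SNP loci
## (position, rsid, region/effect class, gene) are the published ones;
## alleles, depths and qualities are fixture values, documented as such,
## because the source table does not print them.

wdm_candidate_table <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr2", "chr2", "chr3", "chr5", "chr7", "chr8",
              "chr10", "chr19", "chr19", "chr19", "chr22", "chrX"),
    pos = c(16535487L, 69049697L, 70439862L, 10082028L, 114916295L,
            70240520L, 113655825L, 24833705L, 1356844L, 1370741L,
            32131143L, 45937910L, 68424972L),
    rsid = c("rs143314517", "rs199643431", "", "rs186545410", "rs201468090",
             "rs145296947", "", "rs1888656", "rs118122389", "rs199763366",
             "", "", ""),
    class = c("nonsynonymous", "nonsynonymous", "nonsynonymous", "intronic",
              "nonsynonymous", "intronic", "intronic", "intronic",
              "intronic", "synonymous", "intergenic", "intronic",
              "intergenic"),
    gene = c("ARHGEF19", "ARHGAP25", "TIA1", "FANCD2", "TICAM2", "AUTS2",
             "CSMD3", "KIAA1217", "MUM1", "MUM1", "", "FBLN1", ""))
}

# Tiny single-exon coding gene whose CDS is ATG|GCT|TAA centred on `pos`
# (pos sits at codon 2, base 2): a C>T there reads GCT -> GTT, Ala -> Val.
wdm_coding_gene <- function(gene, chrom, pos) {
  data.table::data.table(
    gene_symbol = gene, transcript_id = paste0(gene, "-t1"), chrom = chrom,
    strand = "+", tx_start = pos - 4L, tx_end = pos + 4L,
    cds_start = pos - 4L, cds_end = pos + 4L,
    exon_starts = list(pos - 4L), exon_ends = list(pos + 4L),
    cds_seq = "ATGGCTTAA")
}

# Two-exon gene with `pos` deep inside the intron (1901 bp from either
# junction, far outside any splice window).
wdm_intronic_gene <- function(gene, chrom, pos) {
  data.table::data.table(
    gene_symbol = gene, transcript_id = paste0(gene, "-t1"), chrom = chrom,
    strand = "+", tx_start = pos - 2000L, tx_end = pos + 2000L,
    cds_start = pos - 1950L, cds_end = pos + 1952L,
    exon_starts = list(c(pos - 2000L, pos + 1901L)),
    exon_ends = list(c(pos - 1901L, pos + 2000L)),
    cds_seq = paste0("ATG", strrep("GCT", 32L), "TAA"))
}

wdm_gene_models <- function() {
  cand <- wdm_candidate_table()
  p <- function(g) cand[cand$gene == g]$pos[1]
  mum1_cds <- 1370741L - 5L  # candidate at CDS offset 5: codon 2, base 3
  mum1 <- data.table::data.table(
    gene_symbol = "MUM1", transcript_id = "MUM1-t1", chrom = "chr19",
    strand = "+", tx_start = 1356000L, tx_end = mum1_cds + 8L,
    cds_start = mum1_cds, cds_end = mum1_cds + 8L,
    exon_starts = list(c(1356000L, mum1_cds)),
    exon_ends = list(c(1356100L, mum1_cds + 8L)),
    cds_seq = "ATGGCTTAA")
  data.table::rbindlist(list(
    wdm_coding_gene("ARHGEF19", "chr1", p("ARHGEF19")),
    wdm_coding_gene("ARHGAP25", "chr2", p("ARHGAP25")),
    wdm_coding_gene("TIA1", "chr2", p("TIA1")),
    wdm_coding_gene("TICAM2", "chr5", p("TICAM2")),
    wdm_intronic_gene("FANCD2", "chr3", p("FANCD2")),
    wdm_intronic_gene("AUTS2", "chr7", p("AUTS2")),
    wdm_intronic_gene("CSMD3", "chr8", p("CSMD3")),
    wdm_intronic_gene("KIAA1217", "chr10", p("KIAA1217")),
    wdm_intronic_gene("FBLN1", "chr22", p("FBLN1")),
    mum1))
}

wdm_alleles <- function(cand) {
  # coding candidates read GCT at codon 2; synonymous one sits on base 3
  ref <- ifelse(cand$class == "nonsynonymous", "C",
                ifelse(cand$class == "synonymous", "T", "G"))
  alt <- ifelse(cand$class == "nonsynonymous", "T",
                ifelse(cand$class == "synonymous", "A", "A"))
  cand[, c("ref", "alt") := .(ref, alt)]
  cand
}

#' Build the worked-example store and filter specification
#'
#' Constructs a store holding two affected in-group exomes (`WDM1`, `WDM2`)
#' that both carry the 13 published candidate SNP loci (plus two synthetic
#' candidate indels exercising the indel path), and `n_filter` filter-group
#' samples carrying decoy variants that each violate exactly one filter
#' condition: carried by two or more filter-group samples, flagged
#' dbSNP-common, or carried by only one of the two in-group samples. Two of
#' the candidates are given exactly one filter-group carrier to exercise the
#' at-most-one boundary. Gene models are crafted so that the import-time
#' annotator reproduces the published region/effect classes and gene
#' symbols, and the published rsids are loaded as non-common dbSNP rows.
#'
#' @param dir directory for the fixture (created; the store goes in
#'   `dir/store`).
#' @param n_filter number of filter-group samples (at least 20).
#' @return a list: `store`, `spec` (the [filter_spec()] of the screen:
#'   in-group = the two affected, everyone else filter-group,
#'   `min_in_fraction = 1`, `max_filter_count = 1`,
#'   `exclude_dbsnp = "common_only"`), `candidates` (the expected SNP table),
#'   `decoys` (key -> violated condition), and `dir`.
#' @export
build_wdm_fixture <- function(dir = tempfile("wdm"), n_filter = 22L) {
  stopifnot(n_filter >= 20L)
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  cand <- wdm_alleles(wdm_candidate_table())
  models <- wdm_gene_models()
  gm_path <- file.path(dir, "genes.refflat.tsv")
  write_gene_models(models, gm_path)

  decoys <- data.table::data.table(
    chrom = c("chr4", "chr6", "chr11", "chr13"),
    pos = c(5000000L, 6000000L, 7000000L, 9000000L),
    ref = c("A", "T", "G", "G"),
    alt = c("G", "C", "T", "C"),
    violates = c("dbsnp_common", "two_filter_carriers", "one_in_group_only",
                 "dbsnp_common_and_many_filter_carriers"))

  dbsnp <- rbind(
    cand[rsid != "", .(chrom, pos, ref, alt, rsid, common_flag = FALSE)],
    data.table::data.table(chrom = "chr4", pos = 5000000L, ref = "A",
                           alt = "G", rsid = "rs99000001", common_flag = TRUE),
    data.table::data.table(chrom = "chr13", pos = 9000000L, ref = "G",
                           alt = "C", rsid = "rs99000002", common_flag = TRUE))
  db_path <- file.path(dir, "dbsnp.tsv")
  data.table::fwrite(dbsnp, db_path, sep = "\t", quote = FALSE)

  arhgap <- cand[gene == "ARHGAP25"]
  tia1 <- cand[gene == "TIA1"]
  scores <- data.table::data.table(
    chrom = c(arhgap$chrom, tia1$chrom), pos = c(arhgap$pos, tia1$pos),
    ref = c(arhgap$ref, tia1$ref), alt = c(arhgap$alt, tia1$alt),
    SIFT = c(0.02, 0.01), PolyPhen2 = c(0.91, 0.98), PhyloP = c(2.1, 2.6),
    LRT = c(0.002, 0.001), MutationTaster = c(0.88, 0.97),
    GERP = c(3.5, 4.1))
  sc_path <- file.path(dir, "scores.tsv")
  data.table::fwrite(scores, sc_path, sep = "\t", quote = FALSE)

  call_row <- function(chrom, pos, ref, alt, zyg = "het",
                       rd = 10L, ad = 8L, q = 90) {
    data.table::data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                           alt = alt, zygosity = zyg, ref_depth = rd,
                           alt_depth = ad, quality = q)
  }
  # both affected carry all 13 candidates heterozygously; the TIA1 call uses
  # the documented fixture depths 14/11 at quality 92
  cand_calls <- data.table::rbindlist(lapply(seq_len(nrow(cand)), function(i) {
    if (cand$gene[i] == "TIA1") {
      call_row(cand$chrom[i], cand$pos[i], cand$ref[i], cand$alt[i],
               rd = 14L, ad = 11L, q = 92)
    } else {
      call_row(cand$chrom[i], cand$pos[i], cand$ref[i], cand$alt[i])
    }
  }))
  cand_indels <- rbind(call_row("chr2", 70500000L, "-", "A"),
                       call_row("chr5", 114920000L, "A", "-"))
  decoy_indel <- call_row("chr6", 6500000L, "T", "-")
  d <- function(i) call_row(decoys$chrom[i], decoys$pos[i], decoys$ref[i],
                            decoys$alt[i])

  fids <- sprintf("F%02d", seq_len(n_filter))
  samples <- list()
  samples[["WDM1"]] <- rbind(cand_calls, d(1), d(2), d(3), d(4),
                             cand_indels, decoy_indel)
  samples[["WDM2"]] <- rbind(cand_calls, d(1), d(2), d(4),
                             cand_indels, decoy_indel)
  for (k in seq_along(fids)) {
    rows <- call_row("chr12", 8000000L + k * 10L, "G", "A")
    if (k <= 2L) rows <- rbind(rows, d(2), decoy_indel)    # shared decoy x2
    if (k <= 10L) rows <- rbind(rows, d(4))                # common, widespread
    if (k == 3L) {                                         # boundary: 1 carrier
      fan <- cand[gene == "FANCD2"]
      rows <- rbind(rows, call_row(fan$chrom, fan$pos, fan$ref, fan$alt))
    }
    if (k == 7L) {
      kia <- cand[gene == "KIAA1217"]
      rows <- rbind(rows, call_row(kia$chrom, kia$pos, kia$ref, kia$alt))
    }
    if (k == 3L) rows <- rbind(rows, decoy_indel)          # indel decoy x3
    samples[[fids[k]]] <- rows
  }

  sheet_rows <- list()
  for (sid in names(samples)) {
    calls <- order_variants(samples[[sid]])
    issnp <- is_snp_key(calls$ref, calls$alt)
    write_internal_variants(calls[issnp],
                            file.path(dir, "calls", paste0(sid, ".snp.tsv")))
    write_internal_variants(calls[!issnp],
                            file.path(dir, "calls", paste0(sid, ".indel.tsv")))
    sheet_rows[[sid]] <- data.table::data.table(
      sample_id = sid,
      description = if (startsWith(sid, "WDM")) "affected" else "cohort",
      platform = "exome", format = "internal",
      snp_path = file.path("calls", paste0(sid, ".snp.tsv")),
      indel_path = file.path("calls", paste0(sid, ".indel.tsv")))
  }
  sheet_path <- file.path(dir, "samples.tsv")
  data.table::fwrite(data.table::rbindlist(sheet_rows), sheet_path,
                     sep = "\t", quote = FALSE)

  store <- init_store(file.path(dir, "store"),
                      annotation = list(gene_models = gm_path,
                                        dbsnp = db_path, scores = sc_path))
  batch_import(store, sheet_path)
  spec <- filter_spec(in_group = c("WDM1", "WDM2"),
                      min_in_fraction = 1, max_filter_count = 1L,
                      variant_table = "snp", exclude_dbsnp = "common_only")
  list(store = store, spec = spec, candidates = cand, decoys = decoys,
       dir = dir)
}
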