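## annotate: import-time functional annotation of variants.
## Region classes follow the usual exome-annotator precedence; coding
## effects are computed from the spliced CDS sequence shipped with the gene
## model fixture, so no reference genome is required.

REGION_CLASSES <- c("exonic", "splicing", "ncRNA", "UTR5", "UTR3",
                    "intronic", "upstream", "downstream", "intergenic")
# Precedence when one position hits several transcripts. exonic/splicing,
# UTR5/UTR3 and upstream/downstream are equal-precedence pairs in spirit;
# the strict order below is the deterministic tie-break.
REGION_RANK <- stats::setNames(seq_along(REGION_CLASSES), REGION_CLASSES)

EFFECT_CLASSES <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                    "frameshift", "nonframeshift", "none")
# Most severe first; used when transcripts disagree.
EFFECT_SEVERITY <- c(stopgain = 1, stoploss = 2, frameshift = 3,
                     nonsynonymous = 4, nonframeshift = 5, synonymous = 6,
                     none = 7)

SCORE_NAMES <- c("SIFT", "PolyPhen2", "PhyloP", "LRT", "MutationTaster", "GERP")

#' Bundle annotation resources for import-time annotation
#'
#' @param gene_models path to a refFlat file (see [read_gene_models()]) or a
#'   gene-model `data.table`, or `NULL` (everything classifies intergenic).
#' @param dbsnp path to a dbSNP-style lookup TSV (`chrom pos ref alt rsid
#'   common_flag`) or `NULL`.
#' @param scores path to a score lookup TSV (`chrom pos ref alt` plus one
#'   column per score: SIFT, PolyPhen2, PhyloP, LRT, MutationTaster, GERP)
#'   or `NULL`.
#' @param splice_window intronic bases around an exon junction reported as
#'   `splicing`; default 2, the canonical donor/acceptor dinucleotide.
#' @return an `annotation_db` object.
#' @export
annotation_db <- function(gene_models = NULL, dbsnp = NULL, scores = NULL,
                          splice_window = 2L) {
  stopifnot(splice_window >= 0L)
  models <- if (is.null(gene_models)) NULL
            else if (is.character(gene_models)) read_gene_models(gene_models)
            else data.table::as.data.table(gene_models)
  db <- if (is.null(dbsnp)) NULL
        else if (is.character(dbsnp)) read_dbsnp_table(dbsnp)
        else data.table::as.data.table(dbsnp)
  sc <- if (is.null(scores)) NULL
        else if (is.character(scores)) read_score_table(scores)
        else data.table::as.data.table(scores)
  if (!is.null(db)) data.table::setkeyv(db, c("chrom", "pos", "ref", "alt"))
  if (!is.null(sc)) data.table::setkeyv(sc, c("chrom", "pos", "ref", "alt"))
  structure(list(models = models, dbsnp = db, scores = sc,
                 splice_window = as.integer(splice_window)),
            class = "annotation_db")
}

#' Read a dbSNP-style lookup table
#' @param path TSV with columns chrom, pos, ref, alt, rsid, common_flag.
#' @return keyed `data.table`.
#' @export
read_dbsnp_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "ref", "alt", "rsid")))
  need <- c("chrom", "pos", "ref", "alt", "rsid", "common_flag")
  if (!all(need %in% names(dt))) {
    stop_input("dbSNP table ", path, " must have columns ", paste(need, collapse = ", "))
  }
  dt[, common_flag := as.logical(common_flag)]
  data.table::setkeyv(dt, c("chrom", "pos", "ref", "alt"))
  dt
}

#' Read a per-variant score lookup table
#' @param path TSV keyed by chrom, pos, ref, alt with one column per score.
#' @return keyed `data.table`.
#' @export
read_score_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "ref", "alt")))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(dt))) {
    stop_input("score table ", path, " must have columns ", paste(need, collapse = ", "))
  }
  for (s in intersect(SCORE_NAMES, names(dt))) dt[, (s) := as.numeric(get(s))]
  data.table::setkeyv(dt, c("chrom", "pos", "ref", "alt"))
  dt
}

classify_one_transcript <- function(pos, m, splice_window) {
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  if (pos >= m$tx_start && pos <= m$tx_end) {
    if (is.na(m$cds_start)) return("ncRNA")
    in_exon <- any(pos >= es & pos <= ee)
    if (in_exon) {
      if (pos >= m$cds_start && pos <= m$cds_end) return("exonic")
      if (pos < m$cds_start) return(if (m$strand == "+") "UTR5" else "UTR3")
      return(if (m$strand == "+") "UTR3" else "UTR5")
    }
    # intronic side: distance to the nearest exon junction
    d_left <- pos - ee[ee < pos]
    d_right <- es[es > pos] - pos
    d <- min(c(d_left, d_right))
    return(if (d <= splice_window) "splicing" else "intronic")
  }
  if (pos < m$tx_start && pos >= m$tx_start - 1000L) {
    return(if (m$strand == "+") "upstream" else "downstream")
  }
  if (pos > m$tx_end && pos <= m$tx_end + 1000L) {
    return(if (m$strand == "+") "downstream" else "upstream")
  }
  NA_character_
}

#' Classify the genomic region of a variant position
#'
#' Each transcript on the chromosome gives the position a candidate class
#' (exonic, splicing within `splice_window` of a junction, UTR5/UTR3,
#' intronic, ncRNA for transcripts without a CDS, upstream/downstream within
#' 1 kb); the highest-precedence class across transcripts wins, with ties
#' broken by gene symbol so results are deterministic. No transcript hit
#' gives `intergenic`.
#'
#' @param chrom,pos the variant position (1-based).
#' @param models gene-model `data.table` (see [read_gene_models()]).
#' @param splice_window intronic bases near a junction called `splicing`.
#' @return `list(region_class, gene_symbol, hits)` where `hits` is one row
#'   per overlapping transcript.
#' @export
classify_region <- function(chrom, pos, models, splice_window = 2L) {
  none <- list(region_class = "intergenic", gene_symbol = "",
               hits = data.table::data.table(gene_symbol = character(),
                                             transcript_id = character(),
                                             region_class = character()))
  if (is.null(models) || nrow(models) == 0L) return(none)
  sel <- which(models$chrom == chrom)
  ms <- models[sel]
  if (nrow(ms) == 0L) return(none)
  cls <- character(nrow(ms))
  for (i in seq_len(nrow(ms))) {
    cls[i] <- classify_one_transcript(pos, ms[i], splice_window)
  }
  hit <- !is.na(cls)
  if (!any(hit)) return(none)
  hits <- data.table::data.table(gene_symbol = ms$gene_symbol[hit],
                                 transcript_id = ms$transcript_id[hit],
                                 region_class = cls[hit])
  best <- hits[order(REGION_RANK[region_class], gene_symbol, transcript_id)][1L]
  list(region_class = best$region_class, gene_symbol = best$gene_symbol,
       hits = hits)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

# 0-based offset of a genomic position within the spliced CDS, plus-strand
# orientation; NA if the position is not CDS-exonic.
cds_offset_plus <- function(pos, m) {
  if (is.na(m$cds_start)) return(NA_integer_)
  es <- pmax(m$exon_starts[[1]], m$cds_start)
  ee <- pmin(m$exon_ends[[1]], m$cds_end)
  keep <- ee >= es
  es <- es[keep]; ee <- ee[keep]
  off <- 0L
  for (i in seq_along(es)) {
    if (pos > ee[i]) { off <- off + (ee[i] - es[i] + 1L); next }
    if (pos >= es[i]) return(off + (pos - es[i]))
    return(NA_integer_)
  }
  NA_integer_
}

#' Reference base of a coding position, read from the model's CDS sequence
#'
#' Convenience for building consistent fixtures: returns the genomic-strand
#' reference base implied by the transcript's `cds_seq` at a CDS position.
#' @param model a single gene-model row.
#' @param pos genomic position inside the CDS.
#' @return single base character.
#' @export
coding_ref_base <- function(model, pos) {
  off <- cds_offset_plus(pos, model)
  if (is.na(off)) stop_input("position ", pos, " is not CDS-exonic in ",
                             model$transcript_id)
  L <- nchar(model$cds_seq)
  if (model$strand == "+") {
    substr(model$cds_seq, off + 1L, off + 1L)
  } else {
    complement_base(substr(model$cds_seq, L - off, L - off))
  }
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop_input("cannot translate codon ", codon)
  aa
}

#' Classify the coding effect of an exonic variant
#'
#' SNVs are classified by translating the reference and alternative codon
#' with the standard genetic code: same amino acid is `synonymous`, a gained
#' stop is `stopgain`, a lost stop is `stoploss`, anything else
#' `nonsynonymous`. Exonic indels are classified by length arithmetic:
#' `(inserted - deleted) mod 3 != 0` is a `frameshift`, otherwise
#' `nonframeshift`. For minus-strand models the alleles are mapped into
#' coding orientation; `cds_seq` is always stored in coding orientation.
#'
#' @param variant a list/row with `chrom`, `pos`, `ref`, `alt`.
#' @param model a single gene-model row whose CDS contains the position.
#' @param cds_seq spliced coding sequence; defaults to the model's `cds_seq`.
#' @return `list(effect_class, context)`; for SNVs `context` holds the
#'   transcript id, 0-based CDS offset, both codons and both amino acids.
#' @export
classify_coding_effect <- function(variant, model, cds_seq = model$cds_seq) {
  if (is_snp_key(variant$ref, variant$alt)) {
    off_plus <- cds_offset_plus(variant$pos, model)
    if (is.na(off_plus)) {
      stop_input("variant ", variant$chrom, ":", variant$pos,
                 " is outside the CDS of ", model$transcript_id)
    }
    if (is.na(cds_seq)) stop_input("no CDS sequence available for ",
                                   model$transcript_id)
    L <- nchar(cds_seq)
    if (model$strand == "+") {
      off <- off_plus; cref <- variant$ref; calt <- variant$alt
    } else {
      off <- L - 1L - off_plus
      cref <- complement_base(variant$ref)
      calt <- complement_base(variant$alt)
    }
    ci <- off %/% 3L; within <- off %% 3L
    codon_ref <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    if (substr(codon_ref, within + 1L, within + 1L) != cref) {
      stop_input("reference allele ", variant$ref, " at ", variant$chrom, ":",
                 variant$pos, " disagrees with the CDS sequence of ",
                 model$transcript_id)
    }
    codon_alt <- codon_ref
    substr(codon_alt, within + 1L, within + 1L) <- calt
    aa_ref <- translate_codon(codon_ref)
    aa_alt <- translate_codon(codon_alt)
    eff <- if (aa_ref == aa_alt) "synonymous"
           else if (aa_alt == "*" && aa_ref != "*") "stopgain"
           else if (aa_ref == "*" && aa_alt != "*") "stoploss"
           else "nonsynonymous"
    return(list(effect_class = eff,
                context = list(transcript_id = model$transcript_id,
                               cds_offset = off, codon_ref = codon_ref,
                               codon_alt = codon_alt, aa_ref = aa_ref,
                               aa_alt = aa_alt)))
  }
  ins <- if (variant$alt == "-") 0L else nchar(variant$alt)
  del <- if (variant$ref == "-") 0L else nchar(variant$ref)
  eff <- if ((ins - del) %% 3L != 0L) "frameshift" else "nonframeshift"
  list(effect_class = eff, context = NULL)
}

#' Look up a variant in a dbSNP-style table
#' @param variant list/row with chrom, pos, ref, alt.
#' @param dbsnp_table keyed table from [read_dbsnp_table()] (or `NULL`).
#' @return `list(rsid, is_dbsnp_common)`; absent keys give `""` / `FALSE`.
#' @export
lookup_dbsnp <- function(variant, dbsnp_table) {
  if (is.null(dbsnp_table)) return(list(rsid = "", is_dbsnp_common = FALSE))
  hit <- dbsnp_table[list(variant$chrom, as.integer(variant$pos),
                          variant$ref, variant$alt), nomatch = NULL]
  if (nrow(hit) == 0L) return(list(rsid = "", is_dbsnp_common = FALSE))
  list(rsid = hit$rsid[1], is_dbsnp_common = isTRUE(hit$common_flag[1]))
}

#' Look up per-variant scores
#' @param variant list/row with chrom, pos, ref, alt.
#' @param score_table keyed table from [read_score_table()] (or `NULL`).
#' @return named numeric vector; missing cells/keys are omitted. Indel keys
#'   return an empty map (the score catalogues cover SNVs only).
#' @export
lookup_scores <- function(variant, score_table) {
  if (is.null(score_table) || !is_snp_key(variant$ref, variant$alt)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  hit <- score_table[list(variant$chrom, as.integer(variant$pos),
                          variant$ref, variant$alt), nomatch = NULL]
  if (nrow(hit) == 0L) return(stats::setNames(numeric(0), character(0)))
  cols <- intersect(SCORE_NAMES, names(hit))
  v <- unlist(hit[1, cols, with = FALSE])
  v[!is.na(v)]
}

#' Annotate one variant against all configured resources
#'
#' Composes [classify_region()], [classify_coding_effect()] (for exonic
#' variants), [lookup_dbsnp()] and [lookup_scores()]. When several
#' transcripts cover an exonic SNV the reported effect (and its gene) is the
#' most severe one (stopgain > stoploss > frameshift > nonsynonymous >
#' nonframeshift > synonymous).
#'
#' @param variant list/row with chrom, pos, ref, alt.
#' @param annodb an [annotation_db()] object.
#' @return a list with region_class, effect_class, gene_symbol, rsid,
#'   is_dbsnp_common and scores.
#' @export
annotate_variant <- function(variant, annodb) {
  reg <- classify_region(variant$chrom, variant$pos, annodb$models,
                         annodb$splice_window)
  effect <- "none"
  gene <- reg$gene_symbol
  if (reg$region_class == "exonic") {
    if (is_snp_key(variant$ref, variant$alt)) {
      ex <- reg$hits[region_class == "exonic"]
      best <- NULL
      for (i in seq_len(nrow(ex))) {
        m <- annodb$models[annodb$models$transcript_id == ex$transcript_id[i] &
                           annodb$models$chrom == variant$chrom][1]
        if (is.na(m$cds_seq)) next
        res <- classify_coding_effect(variant, m)
        if (is.null(best) ||
            EFFECT_SEVERITY[res$effect_class] < EFFECT_SEVERITY[best$effect] ||
            (EFFECT_SEVERITY[res$effect_class] == EFFECT_SEVERITY[best$effect] &&
             m$gene_symbol < best$gene)) {
          best <- list(effect = res$effect_class, gene = m$gene_symbol)
        }
      }
      if (!is.null(best)) { effect <- best$effect; gene <- best$gene }
    } else {
      eff <- classify_coding_effect(variant, NULL, NA)
      effect <- eff$effect_class
    }
  }
  db <- lookup_dbsnp(variant, annodb$dbsnp)
  sc <- lookup_scores(variant, annodb$scores)
  list(region_class = reg$region_class, effect_class = effect,
       gene_symbol = gene, rsid = db$rsid,
       is_dbsnp_common = db$is_dbsnp_common, scores = sc)
}
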