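# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's code paths: they re-read the store's on-disk TSVs with base
# R and recompute results by exhaustive enumeration.

internal_header <- "chrom\tpos\tref\talt\tzygosity\tref_depth\talt_depth\tquality"

write_calls_tsv <- function(path, rows = character()) {
  writeLines(c(internal_header, rows), path)
  path
}

call_line <- function(chrom, pos, ref, alt, zyg = "het", rd = 10, ad = 8, q = 90) {
  paste(chrom, pos, ref, alt, zyg, rd, ad, q, sep = "\t")
}

# A tiny in-code sample: three SNPs + one indel
make_sample_files <- function(dir, sid, snp_rows, indel_rows = character()) {
  snp <- write_calls_tsv(file.path(dir, paste0(sid, ".snp.tsv")), snp_rows)
  ind <- write_calls_tsv(file.path(dir, paste0(sid, ".indel.tsv")), indel_rows)
  list(snp = snp, indel = ind)
}

sheet_line <- function(sid, snp, indel, format = "internal") {
  paste(sid, "desc", "sim", format, snp, indel, sep = "\t")
}

write_sheet <- function(path, lines) {
  writeLines(c("sample_id\tdescription\tplatform\tformat\tsnp_path\tindel_path",
               lines), path)
  path
}

# ---------------------------------------------------------------------------
# Random store builder for the oracle-equivalence trials

random_pool <- function(n_pool, include_indels = TRUE) {
  pos <- sample.int(100000L, n_pool)
  chrom <- sample(c("chr1", "chr2"), n_pool, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n_pool, replace = TRUE)
  alt <- mapply(function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), ref)
  if (include_indels) {
    ind <- runif(n_pool) < 0.2
    for (i in which(ind)) {
      if (runif(1) < 0.5) {
        ref[i] <- "-"
        alt[i] <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                               replace = TRUE), collapse = "")
      } else {
        ref[i] <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                               replace = TRUE), collapse = "")
        alt[i] <- "-"
      }
    }
  }
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                   stringsAsFactors = FALSE)
  df[!duplicated(paste(df$chrom, df$pos, df$alt)), ]
}

# Builds a store of n_samples whose calls are drawn from a shared pool, with
# a dbSNP fixture covering part of the pool (half of it flagged common).
build_random_store <- function(dir, n_samples, n_pool, carrier_prob = 0.4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pool <- random_pool(n_pool)
  ids <- sprintf("S%02d", seq_len(n_samples))
  n_db <- max(1L, floor(nrow(pool) * 0.4))
  db_idx <- sample(nrow(pool), n_db)
  dbsnp <- data.frame(pool[db_idx, ],
                      rsid = sprintf("rs%06d", seq_len(n_db)),
                      common_flag = seq_len(n_db) %% 2 == 0)
  db_path <- file.path(dir, "dbsnp.tsv")
  write.table(dbsnp, db_path, sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "in"), showWarnings = FALSE)
  lines <- character()
  for (sid in ids) {
    carry <- which(runif(nrow(pool)) < carrier_prob)
    rows_snp <- character(); rows_ind <- character()
    for (i in carry) {
      zyg <- if (runif(1) < 0.3) "hom" else "het"
      ln <- call_line(pool$chrom[i], pool$pos[i], pool$ref[i], pool$alt[i], zyg)
      if (nchar(pool$ref[i]) == 1 && nchar(pool$alt[i]) == 1 &&
          pool$ref[i] != "-" && pool$alt[i] != "-") {
        rows_snp <- c(rows_snp, ln)
      } else {
        rows_ind <- c(rows_ind, ln)
      }
    }
    make_sample_files(file.path(dir, "in"), sid, rows_snp, rows_ind)
    lines <- c(lines, sheet_line(sid, file.path("in", paste0(sid, ".snp.tsv")),
                                 file.path("in", paste0(sid, ".indel.tsv"))))
  }
  sheet <- write_sheet(file.path(dir, "sheet.tsv"), lines)
  store <- init_store(file.path(dir, "store"),
                      annotation = list(dbsnp = db_path))
  batch_import(store, sheet)
  list(store = store, ids = ids, pool = pool)
}

random_filter_spec <- function(ids, with_class = FALSE) {
  repeat {
    grp <- sample(c("in", "discard", "filter"), length(ids), replace = TRUE,
                  prob = c(0.4, 0.2, 0.4))
    if (any(grp == "in")) break
  }
  use_count <- runif(1) < 0.5
  filter_spec(
    in_group = ids[grp == "in"],
    discard_group = ids[grp == "discard"],
    filter_group = ids[grp == "filter"],
    min_in_fraction = sample(c(0, 0.25, 0.5, 0.75, 1, round(runif(1), 2)), 1),
    max_filter_fraction = if (use_count) NULL else
      sample(c(0, 0.1, 0.5, 1, round(runif(1), 2)), 1),
    max_filter_count = if (use_count) sample(0:3, 1) else NULL,
    variant_table = sample(c("snp", "indel"), 1),
    class_constraint = if (with_class && runif(1) < 0.3)
      list(data.frame(region_class = "intergenic", effect_class = NA),
           data.frame(region_class = "exonic", effect_class = NA),
           data.frame(region_class = NA, effect_class = "none"))[[
             sample(3, 1)]] else NULL,
    exclude_dbsnp = sample(c("off", "all", "common_only"), 1),
    zygosity_constraint = sample(c("any", "any", "any", "hom_in_group"), 1))
}

# ---------------------------------------------------------------------------
# Brute-force group filter: exhaustive enumeration over every variant, using
# only the store's on-disk files and base R.

brute_group_filter <- function(store, spec) {
  kind <- spec$variant_table
  reg <- read.delim(file.path(store$path, "samples.tsv"), sep = "\t",
                    colClasses = "character")
  all_ids <- reg$sample_id
  fg <- spec$filter_group
  if (is.null(fg)) fg <- setdiff(all_ids, c(spec$in_group, spec$discard_group))
  calls <- list()
  for (sid in all_ids) {
    f <- file.path(store$path, "calls", paste0(sid, ".", kind, ".tsv"))
    d <- read.delim(f, sep = "\t", colClasses = c(
      chrom = "character", ref = "character", alt = "character",
      zygosity = "character"))
    d$vid <- paste(d$chrom, d$pos, d$alt, sep = "|")
    calls[[sid]] <- d
  }
  summ_file <- file.path(store$path, paste0("summary_", kind, ".tsv"))
  summ <- read.delim(summ_file, sep = "\t", colClasses = c(
    vid = "character", chrom = "character", ref = "character",
    alt = "character", rsid = "character", region_class = "character",
    effect_class = "character", gene_symbol = "character"))
  all_vids <- unique(unlist(lapply(calls, function(d) d$vid)))
  need_in <- ceiling(spec$min_in_fraction * length(spec$in_group))
  thr <- if (!is.null(spec$max_filter_count)) spec$max_filter_count else
    floor(spec$max_filter_fraction * length(fg))
  keep <- character()
  for (v in all_vids) {
    n_in <- 0L; n_f <- 0L; all_hom <- TRUE
    for (sid in spec$in_group) {
      d <- calls[[sid]]
      hit <- d[d$vid == v, ]
      if (nrow(hit)) {
        n_in <- n_in + 1L
        if (any(hit$zygosity != "hom")) all_hom <- FALSE
      }
    }
    for (sid in fg) {
      if (v %in% calls[[sid]]$vid) n_f <- n_f + 1L
    }
    if (n_in < need_in || n_f > thr) next
    if (spec$zygosity_constraint == "hom_in_group" && !all_hom) next
    srow <- summ[summ$vid == v, ]
    if (nrow(srow) != 1L) stop("oracle: variant missing from summary: ", v)
    if (spec$exclude_dbsnp == "all" &&
        !is.na(srow$rsid) && nzchar(srow$rsid)) next
    if (spec$exclude_dbsnp == "common_only" && isTRUE(srow$dbsnp_common)) next
    if (!is.null(spec$class_constraint)) {
      cc <- spec$class_constraint
      ok <- FALSE
      for (i in seq_len(nrow(cc))) {
        r_ok <- is.na(cc$region_class[i]) ||
          srow$region_class == cc$region_class[i]
        e_ok <- is.na(cc$effect_class[i]) ||
          srow$effect_class == cc$effect_class[i]
        if (r_ok && e_ok) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    keep <- c(keep, v)
  }
  sort(keep)
}

# ---------------------------------------------------------------------------
# Brute-force per-base region classifier: enumerates the position set of
# every class for each transcript, then applies the precedence order.

region_rank_oracle <- c(exonic = 1, splicing = 2, ncRNA = 3, UTR5 = 4,
                        UTR3 = 5, intronic = 6, upstream = 7, downstream = 8,
                        intergenic = 9)

brute_classify_region <- function(chrom, pos, models, splice_window = 2) {
  best <- "intergenic"; best_gene <- ""
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    if (m$chrom != chrom) next
    es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
    exon_pos <- unlist(mapply(seq, es, ee, SIMPLIFY = FALSE))
    tx_pos <- seq(m$tx_start, m$tx_end)
    cls <- NA_character_
    if (pos %in% tx_pos) {
      if (is.na(m$cds_start)) {
        cls <- "ncRNA"
      } else if (pos %in% exon_pos) {
        cds_pos <- seq(m$cds_start, m$cds_end)
        if (pos %in% cds_pos) {
          cls <- "exonic"
        } else if (pos < m$cds_start) {
          cls <- if (m$strand == "+") "UTR5" else "UTR3"
        } else {
          cls <- if (m$strand == "+") "UTR3" else "UTR5"
        }
      } else {
        splice_pos <- integer()
        for (e in seq_along(es)) {
          splice_pos <- c(splice_pos, seq(ee[e] + 1, ee[e] + splice_window),
                          seq(es[e] - splice_window, es[e] - 1))
        }
        splice_pos <- intersect(setdiff(tx_pos, exon_pos), splice_pos)
        cls <- if (pos %in% splice_pos) "splicing" else "intronic"
      }
    } else if (pos %in% seq(m$tx_start - 1000, m$tx_start - 1)) {
      cls <- if (m$strand == "+") "upstream" else "downstream"
    } else if (pos %in% seq(m$tx_end + 1, m$tx_end + 1000)) {
      cls <- if (m$strand == "+") "downstream" else "upstream"
    }
    if (is.na(cls)) next
    if (region_rank_oracle[cls] < region_rank_oracle[best] ||
        (region_rank_oracle[cls] == region_rank_oracle[best] &&
         best_gene != "" && m$gene_symbol < best_gene)) {
      best <- cls; best_gene <- m$gene_symbol
    }
  }
  list(region_class = best, gene_symbol = best_gene)
}

# Leftmost equivalent indel placement, found by exhaustive search: every
# (offset, block) whose deletion from / insertion into REF yields ALT.
brute_leftmost_indel <- function(pos, ref, alt) {
  if (nchar(ref) > nchar(alt)) {        # deletion
    d <- nchar(ref) - nchar(alt)
    for (o in 0:(nchar(ref) - d)) {
      kept <- paste0(substr(ref, 1, o), substr(ref, o + d + 1, nchar(ref)))
      if (kept == alt) {
        return(list(pos = pos + o, ref = substr(ref, o + 1, o + d), alt = "-"))
      }
    }
  } else {                               # insertion
    d <- nchar(alt) - nchar(ref)
    for (o in 0:nchar(ref)) {
      cand <- paste0(substr(ref, 1, o), substr(alt, o + 1, o + d),
                     substr(ref, o + 1, nchar(ref)))
      if (cand == alt) {
        return(list(pos = pos + o - 1, ref = "-",
                    alt = substr(alt, o + 1, o + d)))
      }
    }
  }
  stop("no indel placement found for ", ref, ">", alt)
}
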