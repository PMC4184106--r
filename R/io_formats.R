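## io_formats: every external file the system reads or writes.
## All variant input is normalized to the internal representation
## (1-based positions, "-" for the empty allele) before it reaches the store.

INTERNAL_COLS <- c("chrom", "pos", "ref", "alt", "zygosity",
                   "ref_depth", "alt_depth", "quality")

#' Read variant calls in the internal TSV format
#'
#' The internal format is a tab-separated file with header
#' `chrom pos ref alt zygosity ref_depth alt_depth quality`, one call per
#' row, positions 1-based, `"-"` denoting the empty allele of a pure
#' insertion/deletion. Every external format is converted to this layout
#' before import.
#'
#' @param path path to the TSV file.
#' @param kind `"snp"` or `"indel"`; rows of the other kind are rejected.
#' @return a `data.table` with the eight internal columns, in file order.
#' @export
read_internal_variants <- function(path, kind = c("snp", "indel")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("variant file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "ref", "alt", "zygosity")))
  if (!identical(names(dt), INTERNAL_COLS)) {
    stop_input("malformed internal variant file ", path,
               ": expected columns ", paste(INTERNAL_COLS, collapse = ", "))
  }
  if (nrow(dt) == 0L) return(dt)
  validate_calls(dt, kind, path)
  dt
}

validate_calls <- function(dt, kind, where) {
  line <- function(i) paste0(where, " line ", i + 1L)  # +1 for the header
  bad <- which(!dt$zygosity %in% c("het", "hom"))
  if (length(bad)) stop_input("invalid zygosity at ", line(bad[1]))
  bad <- which(dt$alt_depth < 1L)
  if (length(bad)) stop_input("alt_depth must be >= 1 at ", line(bad[1]))
  bad <- which(dt$ref_depth < 0L | dt$quality < 0)
  if (length(bad)) stop_input("negative depth/quality at ", line(bad[1]))
  keyerr <- tryCatch({
    check_variant_key(dt$chrom, dt$pos, dt$ref, dt$alt, paste0("in ", where))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(keyerr)) stop_input(keyerr)
  issnp <- is_snp_key(dt$ref, dt$alt)
  bad <- if (kind == "snp") which(!issnp) else which(issnp)
  if (length(bad)) {
    stop_input("variant of the wrong kind (expected ", kind, ") at ", line(bad[1]))
  }
  invisible(TRUE)
}

#' Write variant calls in the internal TSV format
#' @param calls a data.table/data.frame with the internal columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_internal_variants <- function(calls, path) {
  calls <- data.table::as.data.table(calls)[, INTERNAL_COLS, with = FALSE]
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Normalize a VCF-style allele pair to the internal representation
#'
#' VCF represents indels with an anchored base (`AT > A`); the internal
#' representation uses the minimal changed alleles with `"-"` for the empty
#' side. The rule: strip the maximal common prefix, then the maximal common
#' suffix, then left-align pure deletions/insertions against the allele
#' string itself (no reference genome is consulted). For a pure insertion
#' `pos` is the base *after which* the sequence is inserted; for all other
#' keys it is the first affected base. Already-normalized keys (containing
#' `"-"`, or with nothing to strip) are returned unchanged, making the
#' operation idempotent.
#'
#' @param pos 1-based POS of the VCF record.
#' @param ref,alt REF and one ALT allele (no commas).
#' @return a list with elements `pos`, `ref`, `alt`.
#' @export
normalize_vcf_allele <- function(pos, ref, alt) {
  if (ref == "-" || alt == "-") return(list(pos = pos, ref = ref, alt = alt))
  if (ref == alt) stop_input("ref equals alt at pos ", pos)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # maximal common prefix
  p <- 0L
  while (p < min(length(r), length(a)) && r[p + 1L] == a[p + 1L]) p <- p + 1L
  # maximal common suffix of the remainders
  s <- 0L
  while (s < min(length(r), length(a)) - p &&
         r[length(r) - s] == a[length(a) - s]) s <- s + 1L
  rr <- r[seq_len(length(r) - s)]
  aa <- a[seq_len(length(a) - s)]
  if (p > 0L) {
    rr <- rr[-seq_len(p)]
    aa <- aa[-seq_len(p)]
  }
  if (length(rr) > 0L && length(aa) > 0L) {
    return(list(pos = pos + p, ref = paste(rr, collapse = ""),
                alt = paste(aa, collapse = "")))
  }
  if (length(rr) > 0L) {             # pure deletion of D starting at q
    q <- pos + p
    d <- length(rr)
    # left-align within the REF string: shift while the base before the
    # deleted block equals its last base
    off <- p                          # 0-based offset of block start in r
    while (off > 0L && r[off] == r[off + d]) {
      off <- off - 1L
      q <- q - 1L
    }
    return(list(pos = q,
                ref = paste(r[off + seq_len(d)], collapse = ""), alt = "-"))
  }
  # pure insertion of I after base q
  q <- pos + p - 1L
  ins <- aa
  j <- p                              # anchor bases available on the left (in a)
  while (j > 0L && a[j] == ins[length(ins)]) {
    ins <- c(ins[length(ins)], ins[-length(ins)])
    j <- j - 1L
    q <- q - 1L
  }
  list(pos = q, ref = "-", alt = paste(ins, collapse = ""))
}

#' Read a single-sample VCF into internal SNP and indel calls
#'
#' Each ALT allele of each record becomes an independent call (multi-allelic
#' records are split); anchored indel alleles are normalized with
#' [normalize_vcf_allele()]. Genotypes with one ALT copy map to `het`, two
#' copies to `hom`; `0/0` and `./.` records are skipped; half-calls such as
#' `./1` are rejected. Depths come from `AD` when present, else from `DP`
#' (as the alt depth, with a warning), else the placeholder 0/1 with a
#' warning.
#'
#' @param path path to a single-sample VCF (plain text or bgzipped).
#' @return `list(snps = data.table, indels = data.table)` in internal layout.
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop_input("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    zygosity = character(), ref_depth = integer(), alt_depth = integer(),
    quality = numeric())
  if (nrow(v@fix) == 0L) return(list(snps = empty, indels = empty))
  if (ncol(v@gt) != 2L) {
    stop_input("expected a single-sample VCF, found ", ncol(v@gt) - 1L,
               " sample columns in ", path)
  }
  fix <- v@fix   # always a matrix, even for a single record
  out <- vector("list", nrow(fix))
  warned_depth <- FALSE
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(v@gt[i, 1L], ":", fixed = TRUE)[[1]]
    val <- strsplit(v@gt[i, 2L], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i) || gt_i > length(val)) {
      stop_input("record ", i, " in ", path, " has no GT field")
    }
    gt <- strsplit(val[gt_i], "[/|]")[[1]]
    if (all(gt == ".")) next
    if (any(gt == ".")) stop_input("half-call genotype '", val[gt_i],
                                   "' at record ", i, " in ", path)
    gt <- as.integer(gt)
    if (all(gt == 0L)) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ad_i <- match("AD", fmt)
    dp_i <- match("DP", fmt)
    ad <- if (!is.na(ad_i) && ad_i <= length(val) && val[ad_i] != ".") {
      suppressWarnings(as.integer(strsplit(val[ad_i], ",", fixed = TRUE)[[1]]))
    } else NULL
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    if (is.na(qual)) qual <- 0
    recs <- list()
    for (k in sort(unique(gt[gt > 0L]))) {
      if (k > length(alts)) stop_input("GT allele index out of range at record ",
                                       i, " in ", path)
      zyg <- if (sum(gt == k) >= 2L) "hom" else "het"
      if (!is.null(ad) && length(ad) >= k + 1L && !anyNA(ad[c(1L, k + 1L)])) {
        rd <- ad[1L]; adep <- ad[k + 1L]
      } else if (!is.na(dp_i) && dp_i <= length(val)) {
        rd <- 0L; adep <- suppressWarnings(as.integer(val[dp_i]))
        if (is.na(adep)) adep <- 1L
        if (!warned_depth) {
          warning("no AD field in ", path, "; using DP as alt depth",
                  call. = FALSE)
          warned_depth <- TRUE
        }
      } else {
        rd <- 0L; adep <- 1L
        if (!warned_depth) {
          warning("no AD/DP depth information in ", path,
                  "; recording placeholder depths 0/1", call. = FALSE)
          warned_depth <- TRUE
        }
      }
      key <- normalize_vcf_allele(as.integer(fix[i, "POS"]), fix[i, "REF"], alts[k])
      recs[[length(recs) + 1L]] <- data.table::data.table(
        chrom = fix[i, "CHROM"], pos = key$pos, ref = key$ref, alt = key$alt,
        zygosity = zyg, ref_depth = rd, alt_depth = max(adep, 1L),
        quality = qual)
    }
    out[[i]] <- data.table::rbindlist(recs)
  }
  calls <- data.table::rbindlist(out)
  if (nrow(calls) == 0L) return(list(snps = empty, indels = empty))
  issnp <- is_snp_key(calls$ref, calls$alt)
  list(snps = calls[issnp], indels = calls[!issnp])
}

SHEET_COLS <- c("sample_id", "description", "platform", "format",
                "snp_path", "indel_path")

#' Read a batch-import sample sheet
#'
#' Tab-separated with header `sample_id description platform format snp_path
#' indel_path`; one row per sample. `format` is `"internal"` or `"vcf"` (for
#' VCF rows, `snp_path` names the VCF and `indel_path` may be `"-"`).
#' Relative paths are resolved against the sheet's directory.
#'
#' @param path path to the sheet.
#' @return a `data.table` of validated rows in file order.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("sample sheet not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!identical(names(dt), SHEET_COLS)) {
    stop_input("sample sheet ", path, " must have columns ",
               paste(SHEET_COLS, collapse = ", "))
  }
  if (anyDuplicated(dt$sample_id)) {
    stop_input("duplicate sample_id in sheet: ",
               paste(unique(dt$sample_id[duplicated(dt$sample_id)]), collapse = ", "))
  }
  if (any(!nzchar(dt$sample_id))) stop_input("empty sample_id in sheet ", path)
  if (any(!dt$format %in% c("internal", "vcf"))) {
    stop_input("unknown format value in sheet ", path, " (use internal|vcf)")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(p == "-" | p == "", p,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  dt[, c("snp_path", "indel_path") := .(resolve(snp_path), resolve(indel_path))]
  for (i in seq_len(nrow(dt))) {
    need <- dt$snp_path[i]
    if (dt$format[i] == "internal") need <- c(need, dt$indel_path[i])
    need <- setdiff(need, c("-", ""))
    miss <- need[!file.exists(need)]
    if (length(miss)) {
      stop_input("sample ", dt$sample_id[i], ": file not found: ",
                 paste(miss, collapse = ", "))
    }
  }
  dt
}

#' Read gene models from a refFlat/genePred file
#'
#' Expects the refFlat column layout (`geneName name chrom strand txStart
#' txEnd cdsStart cdsEnd exonCount exonStarts exonEnds`), 0-based half-open
#' on disk, plus an optional trailing `cdsSeq` column carrying the spliced
#' coding sequence in coding orientation (used by the coding-effect
#' classifier so that no reference genome is needed). Coordinates are
#' converted to the internal 1-based inclusive convention; models with
#' `cdsStart == cdsEnd` are non-coding and get `NA` cds bounds.
#'
#' @param path path to the file.
#' @return a `data.table` with one row per transcript; `exon_starts` /
#'   `exon_ends` are list-columns of 1-based inclusive coordinates.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_input("gene model file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  if (!all(need %in% names(dt))) {
    stop_input("gene model file ", path, " lacks refFlat columns: ",
               paste(setdiff(need, names(dt)), collapse = ", "))
  }
  parse_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  out <- data.table::data.table(
    gene_symbol = dt$geneName, transcript_id = dt$name, chrom = dt$chrom,
    strand = dt$strand,
    tx_start = as.integer(dt$txStart) + 1L, tx_end = as.integer(dt$txEnd),
    cds_start = as.integer(dt$cdsStart) + 1L, cds_end = as.integer(dt$cdsEnd),
    exon_starts = lapply(parse_list(dt$exonStarts), function(v) v + 1L),
    exon_ends = parse_list(dt$exonEnds),
    cds_seq = if ("cdsSeq" %in% names(dt)) dt$cdsSeq else NA_character_)
  # cdsStart == cdsEnd on disk marks a non-coding transcript
  nc <- as.integer(dt$cdsStart) == as.integer(dt$cdsEnd)
  out[nc, c("cds_start", "cds_end") := .(NA_integer_, NA_integer_)]
  out[cds_seq == "" | cds_seq == "-", cds_seq := NA_character_]
  ec <- as.integer(dt$exonCount)
  for (i in seq_len(nrow(out))) {
    if (length(out$exon_starts[[i]]) != ec[i]) {
      stop_input("exonCount disagrees with exon list at ", path, " row ", i)
    }
    validate_gene_model(out[i], paste0(path, " row ", i))
  }
  out
}

validate_gene_model <- function(m, where) {
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  if (length(es) != length(ee)) stop_input("exon list length mismatch at ", where)
  if (length(es) == 0L) stop_input("no exons at ", where)
  if (is.na(m$strand) || !m$strand %in% c("+", "-")) {
    stop_input("strand must be + or - at ", where)
  }
  if (any(ee < es)) stop_input("exon end before start at ", where)
  if (is.unsorted(es, strictly = TRUE) ||
      any(es[-1] <= ee[-length(ee)])) {
    stop_input("exons must be sorted and non-overlapping at ", where)
  }
  if (es[1] < m$tx_start || ee[length(ee)] > m$tx_end) {
    stop_input("exons outside tx span at ", where)
  }
  if (!is.na(m$cds_start)) {
    if (m$cds_start < m$tx_start || m$cds_end > m$tx_end || m$cds_start > m$cds_end) {
      stop_input("cds span outside tx span at ", where)
    }
    L <- cds_length(m)
    if (L %% 3L != 0L) stop_input("CDS length ", L, " not a multiple of 3 at ", where)
    if (!is.na(m$cds_seq) && nchar(m$cds_seq) != L) {
      stop_input("cdsSeq length ", nchar(m$cds_seq),
                 " disagrees with CDS length ", L, " at ", where)
    }
  }
  invisible(TRUE)
}

cds_length <- function(m) {
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  sum(pmax(0L, pmin(ee, m$cds_end) - pmax(es, m$cds_start) + 1L))
}

#' Write gene models in the refFlat layout read by [read_gene_models()]
#' @param models a data.table as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  fmt_list <- function(v) vapply(v, function(x) paste0(paste(x, collapse = ","), ","), "")
  cds_start <- ifelse(is.na(models$cds_start), models$tx_start - 1L, models$cds_start - 1L)
  cds_end <- ifelse(is.na(models$cds_end), models$tx_start - 1L, models$cds_end)
  out <- data.table::data.table(
    geneName = models$gene_symbol, name = models$transcript_id,
    chrom = models$chrom, strand = models$strand,
    txStart = models$tx_start - 1L, txEnd = models$tx_end,
    cdsStart = cds_start, cdsEnd = cds_end,
    exonCount = lengths(models$exon_starts),
    exonStarts = fmt_list(lapply(models$exon_starts, function(v) v - 1L)),
    exonEnds = fmt_list(models$exon_ends),
    cdsSeq = ifelse(is.na(models$cds_seq), "-", models$cds_seq))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
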