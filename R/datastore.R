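## datastore: the warehouse. A store is a directory holding
##   samples.tsv                 sample registry
##   calls/<id>.{snp,indel}.tsv  per-sample call tables
##   summary_{snp,indel}.tsv     denormalized summary tables (1 row/variant)
##   carriers_{snp,indel}.tsv    carrier link tables (variant, sample, zygosity)
##   annotation/ + meta.json     annotation resources and schema metadata
## All tables are kept in memory as keyed data.tables and rewritten after
## every mutating operation; a sample import is staged on copies and only
## committed when the whole import succeeded.

SCHEMA_VERSION <- 1L

SUMMARY_COLS <- c("vid", "chrom", "pos", "ref", "alt", "n_carriers", "rsid",
                  "dbsnp_common", "region_class", "effect_class",
                  "gene_symbol", SCORE_NAMES)

empty_summary <- function() {
  dt <- data.table::data.table(
    vid = character(), chrom = character(), pos = integer(), ref = character(),
    alt = character(), n_carriers = integer(), rsid = character(),
    dbsnp_common = logical(), region_class = character(),
    effect_class = character(), gene_symbol = character())
  for (s in SCORE_NAMES) dt[, (s) := numeric(0)]
  data.table::setkeyv(dt, "vid")
  dt
}

empty_carriers <- function() {
  dt <- data.table::data.table(vid = character(), sample_id = character(),
                               zygosity = character())
  data.table::setkeyv(dt, "vid")
  dt
}

empty_registry <- function() {
  data.table::data.table(sample_id = character(), description = character(),
                         platform = character(), import_time = character(),
                         n_snps = integer(), n_indels = integer())
}

new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$tables_opened <- 0L
  e$summary_rows_scanned <- 0L
  e$anno_calls <- 0L
  e
}

#' Initialize an empty variant store
#'
#' @param path directory to create. Must not already contain a store unless
#'   `overwrite = TRUE`.
#' @param annotation optional named list of annotation resource paths:
#'   `gene_models`, `dbsnp`, `scores` (any may be omitted) and
#'   `splice_window`. The files are copied into the store so it remains
#'   self-contained.
#' @param overwrite replace an existing store.
#' @return a `variant_store` handle.
#' @export
init_store <- function(path, annotation = NULL, overwrite = FALSE) {
  meta_path <- file.path(path, "meta.json")
  if (file.exists(meta_path)) {
    if (!overwrite) stop_input("a store already exists at ", path,
                               " (use overwrite = TRUE)")
    unlink(path, recursive = TRUE)
  } else if (dir.exists(path) && length(list.files(path, all.files = TRUE,
                                                   no.. = TRUE)) > 0L) {
    stop_input("directory ", path, " exists and is not empty")
  }
  dir.create(file.path(path, "calls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "annotation"), showWarnings = FALSE)
  anno_meta <- list(gene_models = NULL, dbsnp = NULL, scores = NULL,
                    splice_window = 2L)
  if (!is.null(annotation)) {
    for (res in c("gene_models", "dbsnp", "scores")) {
      src <- annotation[[res]]
      if (is.null(src)) next
      if (!file.exists(src)) stop_input("annotation file not found: ", src)
      dst <- file.path("annotation", paste0(res, ".tsv"))
      file.copy(src, file.path(path, dst), overwrite = TRUE)
      anno_meta[[res]] <- dst
    }
    if (!is.null(annotation$splice_window)) {
      anno_meta$splice_window <- as.integer(annotation$splice_window)
    }
  }
  store <- new.env(parent = emptyenv())
  store$path <- normalizePath(path)
  store$samples <- empty_registry()
  store$summary <- list(snp = empty_summary(), indel = empty_summary())
  store$carriers <- list(snp = empty_carriers(), indel = empty_carriers())
  store$meta <- list(schema_version = SCHEMA_VERSION, annotation = anno_meta)
  store$counters <- new_counters()
  store$annodb <- NULL
  class(store) <- "variant_store"
  persist_store(store)
  store
}

#' Open an existing variant store
#' @param path store directory created by [init_store()].
#' @return a `variant_store` handle.
#' @export
open_store <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_input("no store found at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  store <- new.env(parent = emptyenv())
  store$path <- normalizePath(path)
  store$meta <- meta
  store$samples <- data.table::fread(
    file.path(path, "samples.tsv"), sep = "\t", header = TRUE,
    colClasses = list(character = c("sample_id", "description", "platform",
                                    "import_time")))
  if (nrow(store$samples) == 0L) store$samples <- empty_registry()
  read_tab <- function(name, template) {
    f <- file.path(path, name)
    dt <- data.table::fread(f, sep = "\t", header = TRUE,
                            colClasses = sapply(template, class))
    if (nrow(dt) == 0L) dt <- data.table::copy(template)
    data.table::setkeyv(dt, "vid")
    dt
  }
  store$summary <- list(snp = read_tab("summary_snp.tsv", empty_summary()),
                        indel = read_tab("summary_indel.tsv", empty_summary()))
  store$carriers <- list(snp = read_tab("carriers_snp.tsv", empty_carriers()),
                         indel = read_tab("carriers_indel.tsv", empty_carriers()))
  store$counters <- new_counters()
  store$annodb <- NULL
  class(store) <- "variant_store"
  store
}

persist_store <- function(store) {
  fw <- function(dt, name) data.table::fwrite(dt, file.path(store$path, name),
                                              sep = "\t", quote = FALSE)
  fw(store$samples, "samples.tsv")
  fw(store$summary$snp, "summary_snp.tsv")
  fw(store$summary$indel, "summary_indel.tsv")
  fw(store$carriers$snp, "carriers_snp.tsv")
  fw(store$carriers$indel, "carriers_indel.tsv")
  jsonlite::write_json(store$meta, file.path(store$path, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(store)
}

store_annodb <- function(store) {
  if (!is.null(store$annodb)) return(store$annodb)
  am <- store$meta$annotation
  full <- function(p) if (is.null(p) || length(p) == 0L || is.na(p)) NULL
                      else file.path(store$path, p)
  store$annodb <- annotation_db(gene_models = full(am$gene_models),
                                dbsnp = full(am$dbsnp),
                                scores = full(am$scores),
                                splice_window = am$splice_window %||% 2L)
  store$annodb
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store> ", x$path, "\n", sep = "")
  cat("  samples: ", nrow(x$samples),
      "  distinct SNPs: ", nrow(x$summary$snp),
      "  distinct indels: ", nrow(x$summary$indel), "\n", sep = "")
  invisible(x)
}

call_file <- function(store, sample_id, kind) {
  file.path(store$path, "calls", paste0(sample_id, ".", kind, ".tsv"))
}

#' Read one sample's call table (counts as a per-sample table access)
#' @keywords internal
read_sample_calls <- function(store, sample_id, kind) {
  store$counters$tables_opened <- store$counters$tables_opened + 1L
  read_internal_variants(call_file(store, sample_id, kind), kind)
}

#' Reset the instrumentation counters of a store
#' @param store a `variant_store`.
#' @return the store, invisibly.
#' @export
reset_counters <- function(store) {
  store$counters <- new_counters()
  invisible(store)
}

#' Read the instrumentation counters of a store
#' @param store a `variant_store`.
#' @return list with `tables_opened`, `summary_rows_scanned`, `anno_calls`.
#' @export
get_counters <- function(store) {
  as.list(store$counters)[c("tables_opened", "summary_rows_scanned",
                            "anno_calls")]
}

# Stage the summary/carrier updates for one sample's calls of one kind.
# Returns modified copies; nothing in the store is touched.
stage_calls <- function(store, kind, calls, sample_id) {
  summ <- data.table::copy(store$summary[[kind]])
  carr <- data.table::copy(store$carriers[[kind]])
  if (nrow(calls) == 0L) {
    return(list(summary = summ, carriers = carr, n = 0L))
  }
  calls <- data.table::as.data.table(calls)
  calls[, vid := make_vid(chrom, pos, alt)]
  if (anyDuplicated(calls$vid)) {
    stop_input("sample ", sample_id, " has duplicate ", kind, " variants: ",
               paste(utils::head(unique(calls$vid[duplicated(calls$vid)]), 3),
                     collapse = ", "))
  }
  known <- summ[list(calls$vid), nomatch = NULL]
  if (nrow(known)) {
    chk <- merge(known[, .(vid, ref_store = ref)],
                 calls[, .(vid, ref_new = ref)], by = "vid")
    bad <- chk[chk$ref_store != chk$ref_new]
    if (nrow(bad)) {
      stop_input("reference allele conflict at ", bad$vid[1], ": store has '",
                 bad$ref_store[1], "', sample ", sample_id, " has '",
                 bad$ref_new[1], "'")
    }
  }
  new_calls <- calls[!vid %in% known$vid]
  if (nrow(new_calls)) {
    annodb <- store_annodb(store)
    rows <- vector("list", nrow(new_calls))
    for (i in seq_len(nrow(new_calls))) {
      v <- as.list(new_calls[i, .(chrom, pos, ref, alt)])
      ann <- annotate_variant(v, annodb)
      store$counters$anno_calls <- store$counters$anno_calls + 1L
      row <- data.table::data.table(
        vid = new_calls$vid[i], chrom = v$chrom, pos = v$pos, ref = v$ref,
        alt = v$alt, n_carriers = 0L, rsid = ann$rsid,
        dbsnp_common = ann$is_dbsnp_common, region_class = ann$region_class,
        effect_class = ann$effect_class, gene_symbol = ann$gene_symbol)
      for (s in SCORE_NAMES) {
        row[, (s) := if (s %in% names(ann$scores)) ann$scores[[s]] else NA_real_]
      }
      rows[[i]] <- row
    }
    summ <- rbind(summ, data.table::rbindlist(rows))
    data.table::setkeyv(summ, "vid")
  }
  carr <- rbind(carr, calls[, .(vid, sample_id = sample_id, zygosity)])
  data.table::setkeyv(carr, "vid")
  summ[list(unique(calls$vid)), n_carriers := n_carriers + 1L]
  list(summary = summ, carriers = carr, n = nrow(calls))
}

warn_mixed_chroms <- function(store, chroms) {
  all_ch <- unique(c(store$summary$snp$chrom, store$summary$indel$chrom, chroms))
  pref <- grepl("^chr", all_ch)
  if (any(pref) && any(!pref)) {
    warning("store mixes 'chr'-prefixed and bare chromosome names",
            call. = FALSE)
  }
}

#' Add one sample to the store
#'
#' Parses the sample's SNP and indel calls, writes its per-sample call
#' tables, annotates every variant key not yet present in the corresponding
#' summary table (annotation runs exactly once per distinct variant over the
#' store's lifetime) and extends the carrier sets. The import is atomic: on
#' any failure the store is unchanged. Re-adding an existing `sample_id` is
#' not an error — the sample is skipped with a message, matching batch
#' semantics.
#'
#' @param store a `variant_store`.
#' @param sample_id unique sample identifier.
#' @param snp_path,indel_path call files; for `format = "vcf"`, `snp_path`
#'   names the VCF (which yields both kinds) and `indel_path` is ignored.
#' @param description,platform free-text registry fields.
#' @param format `"internal"` or `"vcf"`.
#' @return invisibly, a list with `status` (`"imported"` or `"skipped"`) and
#'   call counts.
#' @export
add_sample <- function(store, sample_id, snp_path = NULL, indel_path = NULL,
                       description = "", platform = "",
                       format = c("internal", "vcf")) {
  format <- match.arg(format)
  if (sample_id %in% store$samples$sample_id) {
    message("sample ", sample_id, " already in store; skipped")
    return(invisible(list(status = "skipped", n_snps = 0L, n_indels = 0L)))
  }
  if (format == "internal") {
    snps <- read_internal_variants(snp_path, "snp")
    indels <- read_internal_variants(indel_path, "indel")
  } else {
    both <- read_vcf_variants(snp_path)
    snps <- both$snps
    indels <- both$indels
  }
  warn_mixed_chroms(store, c(snps$chrom, indels$chrom))
  st_snp <- stage_calls(store, "snp", snps, sample_id)
  st_ind <- stage_calls(store, "indel", indels, sample_id)
  # commit
  write_internal_variants(snps, call_file(store, sample_id, "snp"))
  write_internal_variants(indels, call_file(store, sample_id, "indel"))
  store$summary$snp <- st_snp$summary
  store$carriers$snp <- st_snp$carriers
  store$summary$indel <- st_ind$summary
  store$carriers$indel <- st_ind$carriers
  store$samples <- rbind(store$samples, data.table::data.table(
    sample_id = sample_id, description = description, platform = platform,
    import_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_snps = st_snp$n, n_indels = st_ind$n))
  persist_store(store)
  invisible(list(status = "imported", n_snps = st_snp$n, n_indels = st_ind$n))
}

#' Import all samples of a sample sheet
#'
#' Rows are processed in order. Samples already registered are skipped; a
#' failing sample (unreadable or invalid files) aborts only that sample and
#' is recorded in the report.
#'
#' @param store a `variant_store`.
#' @param sheet a sample-sheet `data.table` (see [read_sample_sheet()]) or a
#'   path to one.
#' @return a `data.table` report with one row per sheet row (`sample_id`,
#'   `status`, `n_snps`, `n_indels`, `message`), with totals in attribute
#'   `"totals"`.
#' @export
batch_import <- function(store, sheet) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- data.table::as.data.table(sheet)
  rows <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    r <- sheet[i]
    res <- tryCatch({
      out <- withCallingHandlers(
        add_sample(store, r$sample_id, snp_path = r$snp_path,
                   indel_path = r$indel_path, description = r$description,
                   platform = r$platform, format = r$format),
        message = function(m) invokeRestart("muffleMessage"))
      list(status = out$status, n_snps = out$n_snps, n_indels = out$n_indels,
           msg = "")
    }, error = function(e) {
      list(status = "failed", n_snps = 0L, n_indels = 0L,
           msg = conditionMessage(e))
    })
    rows[[i]] <- data.table::data.table(
      sample_id = r$sample_id, status = res$status, n_snps = res$n_snps,
      n_indels = res$n_indels, message = res$msg)
  }
  report <- data.table::rbindlist(rows)
  if (nrow(report) == 0L) {
    report <- data.table::data.table(sample_id = character(),
                                     status = character(), n_snps = integer(),
                                     n_indels = integer(), message = character())
  }
  totals <- list(imported = sum(report$status == "imported"),
                 skipped = sum(report$status == "skipped"),
                 failed = sum(report$status == "failed"))
  data.table::setattr(report, "totals", totals)
  report
}

#' Remove a sample from the store
#'
#' Drops the sample's call tables, removes it from every carrier set, deletes
#' summary rows whose carrier set becomes empty, and updates the registry.
#'
#' @param store a `variant_store`.
#' @param sample_id a registered sample id.
#' @return invisibly, a list with per-kind counts of variants decremented
#'   (still carried by others) and deleted.
#' @export
remove_sample <- function(store, sample_id) {
  if (!sample_id %in% store$samples$sample_id) {
    stop_input("sample ", sample_id, " is not in the store")
  }
  report <- list()
  for (kind in c("snp", "indel")) {
    carr <- store$carriers[[kind]]
    mine <- which(carr$sample_id == sample_id)
    vids <- unique(carr$vid[mine])
    carr <- if (length(mine)) carr[-mine] else carr
    summ <- store$summary[[kind]]
    summ[list(vids), n_carriers := n_carriers - 1L]
    dead <- summ[list(vids), nomatch = NULL][n_carriers <= 0L]$vid
    summ <- summ[!vid %in% dead]
    data.table::setkeyv(summ, "vid")
    data.table::setkeyv(carr, "vid")
    store$carriers[[kind]] <- carr
    store$summary[[kind]] <- summ
    report[[kind]] <- list(decremented = length(setdiff(vids, dead)),
                           deleted = length(dead))
    unlink(call_file(store, sample_id, kind))
  }
  keep_rows <- which(!store$samples$sample_id %in% sample_id)
  store$samples <- store$samples[keep_rows]
  persist_store(store)
  invisible(report)
}

#' Look up the summary record of one variant
#'
#' Exact-key lookup by (chrom, pos, alt); `ref` is accepted for validation.
#' @param store a `variant_store`.
#' @param chrom,pos,alt the variant key.
#' @param ref optional reference allele to cross-check.
#' @return a one-row `data.table` plus a `carriers` attribute, or `NULL` if
#'   the variant is not in the store.
#' @export
get_summary <- function(store, chrom, pos, alt, ref = NULL) {
  v <- make_vid(chrom, pos, alt)
  for (kind in c("snp", "indel")) {
    hit <- store$summary[[kind]][list(v), nomatch = NULL]
    if (nrow(hit)) {
      if (!is.null(ref) && hit$ref[1] != ref) {
        stop_input("ref mismatch for ", v, ": store has ", hit$ref[1])
      }
      out <- data.table::copy(hit)
      data.table::setattr(out, "carriers",
        data.table::copy(store$carriers[[kind]][list(v), nomatch = NULL]))
      data.table::setattr(out, "kind", kind)
      return(out)
    }
  }
  NULL
}

#' Per-sample and global statistics of a store
#'
#' @param store a `variant_store`.
#' @return a list: `samples` (registry with per-sample counts), `totals`
#'   (samples, distinct/total SNPs and indels) and per-kind
#'   `region_tally` / `effect_tally` tables whose counts sum to the distinct
#'   variant counts.
#' @export
store_stats <- function(store) {
  tally <- function(dt, col) {
    if (nrow(dt) == 0L) {
      return(data.table::data.table(class = character(), n = integer()))
    }
    out <- dt[, .N, by = c(col)]
    data.table::setnames(out, c("class", "n"))
    out[order(class)]
  }
  list(
    samples = data.table::copy(store$samples),
    totals = list(
      n_samples = nrow(store$samples),
      distinct_snps = nrow(store$summary$snp),
      distinct_indels = nrow(store$summary$indel),
      total_snp_calls = sum(store$samples$n_snps),
      total_indel_calls = sum(store$samples$n_indels)),
    region_tally = list(snp = tally(store$summary$snp, "region_class"),
                        indel = tally(store$summary$indel, "region_class")),
    effect_tally = list(snp = tally(store$summary$snp, "effect_class"),
                        indel = tally(store$summary$indel, "effect_class")))
}

#' Deterministic audit dump of the whole store
#'
#' One line per distinct variant: kind, key, the sorted carrier list
#' (`sample:zygosity`), and annotation classes — sorted by kind, natural
#' chromosome order, position and alt allele. Two stores are equal exactly
#' when their audit dumps are identical; this is the canonical equality
#' surface used by the consistency tests.
#'
#' @param store a `variant_store`.
#' @return a character vector of lines (header first).
#' @export
audit_dump <- function(store) {
  lines <- "kind\tchrom\tpos\tref\talt\tcarriers\tregion_class\teffect_class\tgene_symbol"
  for (kind in c("snp", "indel")) {
    summ <- order_variants(data.table::copy(store$summary[[kind]]))
    if (nrow(summ) == 0L) next
    carr <- store$carriers[[kind]]
    for (i in seq_len(nrow(summ))) {
      cc <- carr[list(summ$vid[i]), nomatch = NULL]
      cc <- cc[order(cc$sample_id)]
      lines <- c(lines, paste(kind, summ$chrom[i], summ$pos[i], summ$ref[i],
                              summ$alt[i],
                              paste(paste0(cc$sample_id, ":", cc$zygosity),
                                    collapse = ","),
                              summ$region_class[i], summ$effect_class[i],
                              summ$gene_symbol[i], sep = "\t"))
    }
  }
  lines
}

#' Full-scan consistency audit
#'
#' Re-reads every per-sample call table from disk and checks that, for every
#' variant, the summary-table carrier set equals exactly the set of samples
#' whose call tables contain it; that the cached `n_carriers` and registry
#' counts agree; and that no summary row lacks carriers. This is the ground
#' truth check run in tests after mutation sequences.
#'
#' @param store a `variant_store`.
#' @return `TRUE` if consistent, otherwise `FALSE` with the problems in
#'   attribute `"problems"`.
#' @export
audit_check <- function(store) {
  problems <- character()
  for (kind in c("snp", "indel")) {
    truth <- list()
    for (sid in store$samples$sample_id) {
      calls <- read_sample_calls(store, sid, kind)
      ncol_field <- if (kind == "snp") "n_snps" else "n_indels"
      reg_n <- store$samples[store$samples$sample_id == sid][[ncol_field]]
      if (nrow(calls) != reg_n) {
        problems <- c(problems, paste0(sid, " ", kind, ": registry count ",
                                       reg_n, " != file rows ", nrow(calls)))
      }
      if (nrow(calls)) {
        truth[[sid]] <- data.table::data.table(
          vid = make_vid(calls$chrom, calls$pos, calls$alt),
          sample_id = sid, zygosity = calls$zygosity)
      }
    }
    truth <- if (length(truth)) data.table::rbindlist(truth) else empty_carriers()
    carr <- store$carriers[[kind]]
    key <- function(dt) sort(paste(dt$vid, dt$sample_id, dt$zygosity))
    if (!identical(key(truth), key(carr))) {
      problems <- c(problems, paste0(kind, ": carrier link table disagrees ",
                                     "with per-sample call tables"))
    }
    summ <- store$summary[[kind]]
    counts <- if (nrow(truth)) truth[, .N, by = vid] else
      data.table::data.table(vid = character(), N = integer())
    m <- merge(summ[, .(vid, n_carriers)], counts, by = "vid", all = TRUE)
    m[is.na(N), N := 0L]
    bad <- m[is.na(m$n_carriers) | m$n_carriers != m$N | m$N == 0L]
    if (nrow(bad)) {
      problems <- c(problems, paste0(kind, ": summary carrier counts wrong for ",
                                     paste(utils::head(bad$vid, 3), collapse = ", ")))
    }
  }
  ok <- length(problems) == 0L
  if (!ok) attr(ok, "problems") <- problems
  ok
}
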