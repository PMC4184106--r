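## synthdata: download-free synthetic cohorts, toy gene models and
## annotation tables with exactly realized planted truths, plus the
## worked-example fixture reproducing the published candidate-mutation
## screen at desk scale.

#' Describe a planted variant for [generate_cohort()]
#'
#' Carriers are realized exactly, never sampled: an explicit `carriers`
#' list is used as-is; a per-population `freq` map assigns the variant to
#' the first `round(freq * n_pop)` samples of a seed-fixed shuffled order,
#' so scenario truths support equality assertions.
#'
#' @param chrom,pos,ref,alt the variant key (internal representation).
#' @param carriers explicit character vector of carrier sample ids.
#' @param freq named numeric vector: per-population carrier frequency.
#' @param zygosity `"het"` or `"hom"` for all realized carriers.
#' @param scenario free-text label recorded in the truth manifest
#'   (`de_novo`, `dominant`, `recessive`, `population_specific`, ...).
#' @return a `planted_variant` list.
#' @export
planted_variant <- function(chrom, pos, ref, alt, carriers = NULL, freq = NULL,
                            zygosity = "het", scenario = "background") {
  check_variant_key(chrom, pos, ref, alt, "in planted_variant")
  if (is.null(carriers) == is.null(freq)) {
    stop_input("give exactly one of carriers or freq")
  }
  if (!is.null(freq) && (any(freq < 0) || any(freq > 1))) {
    stop_input("planted frequencies must be in [0, 1]")
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 carriers = carriers, freq = freq, zygosity = zygosity,
                 scenario = scenario),
            class = "planted_variant")
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

rand_snp_alleles <- function(n) {
  ref <- rand_base(n)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Generate a synthetic cohort with planted truths
#'
#' Writes one internal-format SNP and indel file per sample, a batch-import
#' sample sheet and a truth manifest under `dir`. Background variation has
#' two components: a shared pool (each sample carries each pool variant
#' independently with `background_carrier_prob`, emulating polymorphisms and
#' recurrent artifacts seen across a cohort) and per-sample private variants
#' (each of `n_private_sites` sample-specific sites is a variant with
#' probability `private_rate`). Planted variants are realized exactly (see
#' [planted_variant()]); background keys that would collide with a planted
#' key are dropped. Output is byte-identical for a fixed seed.
#'
#' @param dir output directory (created).
#' @param populations named integer vector: samples per population label.
#' @param shared_pool_size number of shared background variants.
#' @param background_carrier_prob per-sample carrier probability of each
#'   pool variant.
#' @param private_rate per-site probability of a private variant.
#' @param n_private_sites number of candidate private sites per sample.
#' @param indel_fraction fraction of the shared pool that are indels.
#' @param planted list of [planted_variant()] objects.
#' @param seed integer seed; all randomness flows from it.
#' @return a list: `dir`, `sheet` (path), `truth` (manifest `data.table`),
#'   `sample_ids`, `populations` (named character vector by sample).
#' @export
generate_cohort <- function(dir, populations = c(POP = 6L),
                            shared_pool_size = 30L,
                            background_carrier_prob = 0.3,
                            private_rate = 0.2, n_private_sites = 10L,
                            indel_fraction = 0.2, planted = list(),
                            seed = 1L) {
  stopifnot(all(populations >= 1L), shared_pool_size >= 0L,
            background_carrier_prob >= 0, background_carrier_prob <= 1,
            private_rate >= 0, private_rate <= 1)
  set.seed(seed)
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  pops <- rep(names(populations), populations)
  ids <- unlist(lapply(names(populations), function(lb) {
    w <- max(2L, nchar(as.character(populations[[lb]])))
    sprintf("%s%0*d", lb, w, seq_len(populations[[lb]]))
  }))
  names(pops) <- ids
  # seed-fixed shuffled order per population, used to realize frequencies
  shuffled <- lapply(split(ids, pops[ids]), sample)

  planted_keys <- vapply(planted, function(p) make_vid(p$chrom, p$pos, p$alt), "")
  pool <- data.table::data.table()
  if (shared_pool_size > 0L) {
    pos <- sample(seq(1e6L, 2e6L), shared_pool_size)
    chrom <- paste0("chr", sample(1:4, shared_pool_size, replace = TRUE))
    is_ind <- stats::runif(shared_pool_size) < indel_fraction
    al <- rand_snp_alleles(shared_pool_size)
    ref <- al$ref; alt <- al$alt
    for (i in which(is_ind)) {
      if (stats::runif(1) < 0.5) {
        ref[i] <- "-"; alt[i] <- paste(rand_base(sample(1:3, 1)), collapse = "")
      } else {
        ref[i] <- paste(rand_base(sample(1:3, 1)), collapse = ""); alt[i] <- "-"
      }
    }
    pool <- data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
    pool <- pool[!duplicated(make_vid(chrom, pos, alt))]
    pool <- pool[!make_vid(chrom, pos, alt) %in% planted_keys]
  }

  sample_calls <- stats::setNames(
    lapply(ids, function(x) data.table::data.table()), ids)
  add_call <- function(sid, chrom, pos, ref, alt, zyg) {
    data.table::rbindlist(list(
      sample_calls[[sid]],
      data.table::data.table(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
        zygosity = zyg,
        ref_depth = stats::rbinom(1L, 40L, 0.5),
        alt_depth = 1L + stats::rbinom(1L, 40L, 0.5),
        quality = round(stats::runif(1L, 30, 99), 1))))
  }
  for (sid in ids) {
    if (nrow(pool)) {
      carry <- stats::runif(nrow(pool)) < background_carrier_prob
      for (i in which(carry)) {
        zyg <- if (stats::runif(1) < 0.3) "hom" else "het"
        sample_calls[[sid]] <- add_call(sid, pool$chrom[i], pool$pos[i],
                                        pool$ref[i], pool$alt[i], zyg)
      }
    }
    k <- match(sid, ids)
    for (j in seq_len(n_private_sites)) {
      if (stats::runif(1) < private_rate) {
        al <- rand_snp_alleles(1L)
        sample_calls[[sid]] <- add_call(sid, "chr9",
                                        1e6L + k * 1000L + j,
                                        al$ref, al$alt, "het")
      }
    }
  }

  truth_rows <- list()
  for (p in planted) {
    if (!is.null(p$carriers)) {
      carriers <- p$carriers
      if (!all(carriers %in% ids)) {
        stop_input("planted carriers not in cohort: ",
                   paste(setdiff(carriers, ids), collapse = ", "))
      }
    } else {
      if (!all(names(p$freq) %in% names(populations))) {
        stop_input("planted freq names unknown population")
      }
      carriers <- unlist(lapply(names(p$freq), function(lb) {
        k <- round(p$freq[[lb]] * populations[[lb]])
        utils::head(shuffled[[lb]], k)
      }))
    }
    for (sid in carriers) {
      sample_calls[[sid]] <- add_call(sid, p$chrom, p$pos, p$ref, p$alt,
                                      p$zygosity)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
      chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt,
      kind = if (is_snp_key(p$ref, p$alt)) "snp" else "indel",
      scenario = p$scenario, zygosity = p$zygosity,
      carriers = paste(sort(carriers), collapse = ","))
  }
  truth <- if (length(truth_rows)) data.table::rbindlist(truth_rows) else
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           kind = character(), scenario = character(),
                           zygosity = character(), carriers = character())

  sheet_rows <- list()
  for (sid in ids) {
    calls <- sample_calls[[sid]]
    if (nrow(calls) == 0L) {
      calls <- data.table::data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      zygosity = character(),
                                      ref_depth = integer(),
                                      alt_depth = integer(),
                                      quality = numeric())
    }
    calls <- calls[!duplicated(make_vid(chrom, pos, alt))]
    calls <- order_variants(calls)
    issnp <- is_snp_key(calls$ref, calls$alt)
    snp_f <- file.path(dir, "calls", paste0(sid, ".snp.tsv"))
    ind_f <- file.path(dir, "calls", paste0(sid, ".indel.tsv"))
    write_internal_variants(calls[issnp], snp_f)
    write_internal_variants(calls[!issnp], ind_f)
    sheet_rows[[sid]] <- data.table::data.table(
      sample_id = sid, description = paste0("synthetic ", pops[[sid]]),
      platform = "simulated", format = "internal",
      snp_path = file.path("calls", paste0(sid, ".snp.tsv")),
      indel_path = file.path("calls", paste0(sid, ".indel.tsv")))
  }
  sheet <- data.table::rbindlist(sheet_rows)
  sheet_path <- file.path(dir, "samples.tsv")
  data.table::fwrite(sheet, sheet_path, sep = "\t", quote = FALSE)
  data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE)
  list(dir = dir, sheet = sheet_path, truth = truth, sample_ids = ids,
       populations = pops)
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, max(n_codons - 2L, 0L), replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Generate a toy gene-model and annotation-table fixture
#'
#' Writes a refFlat file (with the `cdsSeq` column), a dbSNP-style lookup
#' table and a score table under `dir`. Genes sit on chromosome `"chrT"`,
#' alternate between strands, have 1-3 exons and internally consistent CDS
#' sequences. About `dbsnp_coverage` of the returned example variant keys
#' get a dbSNP row (half of them flagged common) and half of those get
#' scores, so tests can plant both catalogued and novel variants.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param n_genes number of toy genes.
#' @param dbsnp_coverage fraction of example keys present in the dbSNP table.
#' @return a list: `models` (`data.table`), `gene_models`, `dbsnp`, `scores`
#'   (paths), and `catalog` — example variant keys with their dbSNP status.
#' @export
generate_gene_fixture <- function(dir, seed = 1L, n_genes = 6L,
                                  dbsnp_coverage = 0.4) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (g in seq_len(n_genes)) {
    base <- g * 100000L
    n_ex <- sample(1:3, 1L)
    es <- integer(n_ex); ee <- integer(n_ex)
    cur <- base
    for (e in seq_len(n_ex)) {
      es[e] <- cur
      ee[e] <- cur + sample(60:120, 1L)
      cur <- ee[e] + sample(200:500, 1L)
    }
    cds_start <- es[1] + sample(3:10, 1L)
    cds_end <- ee[n_ex] - sample(3:10, 1L)
    m <- data.table::data.table(
      gene_symbol = sprintf("TOYG%02d", g),
      transcript_id = sprintf("TOYT%02d", g), chrom = "chrT",
      strand = if (g %% 2L == 0L) "-" else "+",
      tx_start = es[1], tx_end = ee[n_ex],
      cds_start = cds_start, cds_end = cds_end,
      exon_starts = list(es), exon_ends = list(ee),
      cds_seq = NA_character_)
    L <- cds_length(m)
    # trim the cds end so the spliced length is a codon multiple
    m$cds_end <- m$cds_end - (L %% 3L)
    L <- cds_length(m)
    m$cds_seq <- random_cds(L %/% 3L)
    rows[[g]] <- m
  }
  models <- data.table::rbindlist(rows)
  gm_path <- file.path(dir, "genes.refflat.tsv")
  write_gene_models(models, gm_path)

  # example variant keys across the fixture genes (exonic keys use the base
  # implied by the CDS sequence so coding-effect calls stay consistent)
  keys <- list()
  for (g in seq_len(nrow(models))) {
    m <- models[g]
    mid_exon <- m$exon_starts[[1]][1]
    p_ex <- max(m$cds_start, mid_exon) + 2L
    ref <- coding_ref_base(m, p_ex)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    keys[[length(keys) + 1L]] <- data.table::data.table(
      chrom = m$chrom, pos = p_ex, ref = ref, alt = alt)
    if (length(m$exon_starts[[1]]) > 1L) {
      p_in <- m$exon_ends[[1]][1] + 50L
      al <- rand_snp_alleles(1L)
      keys[[length(keys) + 1L]] <- data.table::data.table(
        chrom = m$chrom, pos = p_in, ref = al$ref, alt = al$alt)
    }
  }
  al <- rand_snp_alleles(4L)
  keys[[length(keys) + 1L]] <- data.table::data.table(
    chrom = "chrT", pos = seq(5e6L, 5e6L + 3L), ref = al$ref, alt = al$alt)
  catalog <- data.table::rbindlist(keys)
  catalog <- catalog[!duplicated(make_vid(chrom, pos, alt))]
  n_db <- max(1L, round(dbsnp_coverage * nrow(catalog)))
  in_db <- sort(sample(nrow(catalog), n_db))
  catalog[, rsid := ""]
  catalog[, common_flag := FALSE]
  catalog[in_db, rsid := sprintf("rs%07d", sample(1e6L, length(in_db)))]
  catalog[in_db, common_flag := seq_along(in_db) %% 2L == 0L]
  dbsnp <- catalog[in_db, .(chrom, pos, ref, alt, rsid, common_flag)]
  db_path <- file.path(dir, "dbsnp.tsv")
  data.table::fwrite(dbsnp, db_path, sep = "\t", quote = FALSE)

  sc_idx <- in_db[seq_along(in_db) %% 2L == 1L]
  scores <- catalog[sc_idx, .(chrom, pos, ref, alt)]
  scores[, SIFT := round(stats::runif(.N), 3)]
  scores[, PolyPhen2 := round(stats::runif(.N), 3)]
  scores[, PhyloP := round(stats::runif(.N, -2, 6), 2)]
  scores[, LRT := round(stats::runif(.N), 3)]
  scores[, MutationTaster := round(stats::runif(.N), 3)]
  scores[, GERP := round(stats::runif(.N, -3, 6), 2)]
  sc_path <- file.path(dir, "scores.tsv")
  data.table::fwrite(scores, sc_path, sep = "\t", quote = FALSE)

  list(models = models, gene_models = gm_path, dbsnp = db_path,
       scores = sc_path, catalog = catalog)
}
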