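`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural ordering rank for chromosome names
#'
#' Orders "chr1" < "chr2" < ... < "chr22" < "chrX" < "chrY" < "chrM", with or
#' without the "chr" prefix; names that are neither numeric nor X/Y/M sort
#' after those, alphabetically. Used everywhere a deterministic, diffable
#' output order is promised.
#'
#' @param chrom character vector of chromosome names.
#' @return an integer-like order index usable in `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  num[core == "X"] <- 23
  num[core == "Y"] <- 24
  num[core %in% c("M", "MT")] <- 25
  # non-standard names: push past the numeric block, keep alphabetical order
  bad <- is.na(num)
  if (any(bad)) {
    num[bad] <- 1000 + as.integer(factor(core[bad], levels = sort(unique(core[bad]))))
  }
  num
}

#' Order rows of a variant table deterministically
#' @param dt a data.table with chrom, pos, alt columns.
#' @return the reordered data.table.
#' @keywords internal
order_variants <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  dt[order(chrom_rank(chrom), pos, alt)]
}

#' Canonical variant id used as the join key across tables
#'
#' Identity is (chrom, pos, alt), mirroring the summary-table key; ref is
#' carried alongside for validation only.
#' @keywords internal
make_vid <- function(chrom, pos, alt) paste(chrom, as.integer(pos), alt, sep = "|")

stop_input <- function(...) stop(..., call. = FALSE)

#' Validate the allele fields of a variant key
#' @keywords internal
check_variant_key <- function(chrom, pos, ref, alt, where = "") {
  ok_allele <- function(a) {
    a == "-" | (nchar(a) >= 1L & !grepl("[^ACGT]", a))
  }
  bad <- !ok_allele(ref) | !ok_allele(alt)
  if (any(bad)) {
    stop_input("invalid allele string(s) ", where, ": ",
               paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop_input("ref equals alt ", where, " (", paste(
      unique(paste0(chrom[ref == alt], ":", pos[ref == alt])), collapse = ", "), ")")
  }
  if (any(ref == "-" & alt == "-")) stop_input("ref and alt cannot both be '-' ", where)
  if (any(!is.finite(pos)) || any(pos < 1)) stop_input("pos must be >= 1 ", where)
  invisible(TRUE)
}

#' Is a (ref, alt) pair a SNP?
#'
#' A key is a SNP iff both alleles are single bases (neither "-"); everything
#' else (insertions, deletions, multi-base substitutions) lives in the indel
#' table.
#' @param ref,alt allele strings using "-" for the empty allele.
#' @return logical vector.
#' @export
is_snp_key <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref != "-" & alt != "-"
}
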