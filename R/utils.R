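# Internal helpers shared across modules.

# Condition constructors: usage errors (CLI exit 1) vs data/format errors
# (CLI exit 2). Everything user-facing funnels through these.
covote_usage_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covote_usage_error")
}

covote_data_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "covote_data_error")
}

#' Canonicalize a chromosome label
#'
#' Callers and references mix `chr1` and `1` dialects; by default the optional
#' `chr` prefix is stripped so both spell the same chromosome. Pass
#' `strip_chr = FALSE` to compare labels verbatim.
#'
#' @param chrom character vector of chromosome labels.
#' @param strip_chr strip a leading `"chr"` prefix (default `TRUE`).
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
normalize_chrom <- function(chrom, strip_chr = TRUE) {
  if (strip_chr) sub("^chr", "", chrom) else chrom
}

#' Build canonical match keys
#'
#' The identity under which calls from different callers are "the same
#' variant": `chrom:pos:ref:alt` of the normalized (decomposed, trimmed,
#' left-aligned) representation.
#'
#' @param chrom,pos,ref,alt normalized variant fields (vectorized).
#' @return character vector of keys.
#' @export
match_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# SNV iff both alleles are single bases.
variant_class <- function(ref, alt) {
  if_else(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

is_valid_allele <- function(x) {
  nchar(x) > 0L & !str_detect(x, "[^ACGTNacgtn]")
}

is_symbolic_alt <- function(x) {
  str_detect(x, "[<>\\[\\]*]")
}

# Parse a VCF GT string into a list(a, b, phased, missing).
# Haploid GTs ("1") are treated as homozygous for backward tolerance.
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(list(a = NA_integer_, b = NA_integer_, phased = FALSE, missing = TRUE))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  if (any(parts == ".")) {
    return(list(a = NA_integer_, b = NA_integer_, phased = phased, missing = TRUE))
  }
  idx <- suppressWarnings(as.integer(parts))
  if (anyNA(idx)) return(NULL)
  if (length(idx) == 1L) idx <- c(idx, idx)
  if (length(idx) != 2L) return(NULL)
  list(a = idx[1], b = idx[2], phased = phased, missing = FALSE)
}

# Genotype class string for a biallelic genotype over {0,1}; phase ignored,
# 0/1 and 1/0 coincide. 0/0 maps to "hom_ref" (treated upstream as no call).
genotype_class <- function(a, b) {
  n_alt <- (a == 1L) + (b == 1L)
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

# Serialize a genotype class back to a GT string.
gt_string <- function(genotype) {
  dplyr::case_match(genotype, "het" ~ "0/1", "hom_alt" ~ "1/1",
                    "hom_ref" ~ "0/0", .default = "./.")
}

sort_calls <- function(tbl) {
  arrange(tbl, .data$chrom, .data$pos, .data$ref, .data$alt)
}
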