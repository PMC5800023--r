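# Harmonization: multiallelic decomposition, allele trimming and indel
# left-alignment, so that every caller's spelling of the same edit receives
# the same canonical match key. This is the stage the voting engine depends
# on: without it, GATK-, Varscan- and Freebayes-style outputs name the same
# indel at different positions and could never reach a quorum.

#' Load a reference genome for normalization
#'
#' Reads a FASTA into the named-character form used as window provider by
#' [normalize_calls()] and [build_callset()]. Sequence names are
#' canonicalized like chromosome labels in VCF input.
#'
#' @param path FASTA file.
#' @param strip_chr strip a leading `"chr"` from sequence names.
#' @return named character vector, one element per sequence.
#' @export
read_reference_fasta <- function(path, strip_chr = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- normalize_chrom(sub("\\s.*$", "", names(seqs)), strip_chr)
  out
}

#' Write a reference genome as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, width = 70) {
  seqs <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

ref_base <- function(reference, chrom, pos) {
  substr(reference[[chrom]], pos, pos)
}

#' Decompose multiallelic records into biallelic calls
#'
#' Splits each raw VCF record into one row per alternate allele, remapping
#' the genotype onto {REF, ALT} of that allele. Outputs whose remapped
#' genotype would be homozygous-reference or missing do not enter voting (a
#' caller asserting 0/0 at a site did not detect the variant); they are
#' retained in the `attr(, "dropped")` audit table.
#'
#' @param calls raw call table from [read_caller_vcf()].
#' @return tibble with one row per retained allele: `chrom`, `pos`, `ref`,
#'   `alt`, `genotype` (`"het"` or `"hom_alt"`), `caller`, `line`; dropped
#'   alleles in `attr(, "dropped")` with a `reason` column.
#' @export
decompose_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  rows <- vector("list", nrow(calls))
  dropped <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    rec <- calls[i, ]
    alts <- strsplit(rec$alt, ",", fixed = TRUE)[[1]]
    pg <- if (is.na(rec$gt)) {
      list(a = NA_integer_, b = NA_integer_, missing = TRUE)
    } else {
      parse_gt(rec$gt)
    }
    if (!pg$missing && (pg$a > length(alts) || pg$b > length(alts) ||
                        pg$a < 0L || pg$b < 0L)) {
      covote_data_error("genotype index out of range at %s:%d (GT %s, %d ALT allele(s))",
                        rec$chrom, rec$pos, rec$gt, length(alts))
    }
    out <- vector("list", length(alts))
    drp <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      if (pg$missing) {
        gclass <- NA_character_
        reason <- "missing_genotype"
      } else {
        # Remap allele indices onto {0, 1} for this alt.
        a <- as.integer(pg$a == j)
        b <- as.integer(pg$b == j)
        gclass <- genotype_class(a, b)
        reason <- if (gclass == "hom_ref") "hom_ref_after_remap" else NA_character_
      }
      row <- tibble(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                    alt = alts[j], genotype = gclass, caller = rec$caller,
                    line = rec$line)
      if (!is.na(gclass) && gclass != "hom_ref") {
        out[[j]] <- row
      } else {
        row$reason <- reason
        drp[[j]] <- row
      }
    }
    rows[[i]] <- bind_rows(out)
    dropped[[i]] <- bind_rows(drp)
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0L) {
    res <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(),
                  caller = character(), line = integer())
  }
  attr(res, "dropped") <- bind_rows(dropped)
  res
}

#' Trim and left-align one variant
#'
#' Canonicalizes a single (pos, ref, alt) pair: shared suffix bases are
#' trimmed, indels are shifted left through repetitive context while the
#' applied edit is unchanged, then shared prefix bases are trimmed, always
#' keeping at least one base in each allele. The result is a fixpoint:
#' renormalizing changes nothing.
#'
#' With `reference = NULL` the function runs in trim-only mode: prefix/suffix
#' trimming without left-alignment. Keys from trim-only runs are not
#' canonical across spellings that differ by indel placement.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param ref,alt allele strings (nonempty, A/C/G/T/N).
#' @param reference named character vector of chromosome sequences, or `NULL`
#'   for trim-only mode.
#' @param window left-alignment window half-width in bp: shifting stops with
#'   a warning if it would cross `pos - window`.
#' @return list `(pos, ref, alt)` of the normalized spelling.
#' @export
#' @examples
#' ref <- c(`1` = "GGCACACAGG")
#' # deletion of one CA unit, right-shifted spelling:
#' normalize_variant("1", 5, "ACA", "A", reference = ref)
#' # same edit, leftmost spelling:
#' normalize_variant("1", 3, "CAC", "C", reference = ref)
normalize_variant <- function(chrom, pos, ref, alt, reference = NULL,
                              window = 100) {
  if (ref == alt) {
    covote_data_error("ref and alt are identical at %s:%d", chrom, pos)
  }
  trim_only <- is.null(reference)
  left_edge <- max(1L, pos - as.integer(window))
  if (!trim_only) {
    if (!chrom %in% names(reference)) {
      covote_data_error("chromosome '%s' absent from reference", chrom)
    }
    chromseq <- reference[[chrom]]
    if (pos + nchar(ref) - 1L > nchar(chromseq)) {
      covote_data_error("reference mismatch at %s:%d (REF runs past chromosome end)",
                        chrom, pos)
    }
    if (substr(chromseq, pos, pos + nchar(ref) - 1L) != ref) {
      covote_data_error("reference mismatch at %s:%d (REF '%s' != reference '%s')",
                        chrom, pos, ref,
                        substr(chromseq, pos, pos + nchar(ref) - 1L))
    }
  }
  repeat {
    n1 <- nchar(ref); n2 <- nchar(alt)
    if (n1 > 0L && n2 > 0L &&
        substr(ref, n1, n1) == substr(alt, n2, n2) &&
        !(n1 == 1L && n2 == 1L)) {
      if (n1 > 1L && n2 > 1L) {
        # plain shared-suffix trim
        ref <- substr(ref, 1L, n1 - 1L)
        alt <- substr(alt, 1L, n2 - 1L)
      } else {
        # pure indel: drop the last base and extend left from the reference
        if (trim_only) break
        if (pos - 1L < left_edge) {
          warn(sprintf("left-alignment window edge reached at %s:%d; position not fully canonical",
                       chrom, pos))
          break
        }
        b <- ref_base(reference, chrom, pos - 1L)
        ref <- paste0(b, substr(ref, 1L, n1 - 1L))
        alt <- paste0(b, substr(alt, 1L, n2 - 1L))
        pos <- pos - 1L
      }
    } else {
      break
    }
  }
  # shared-prefix trim, keeping >= 1 base in each allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize a table of biallelic calls
#'
#' Applies [normalize_variant()] row-wise and adds the canonical `key` and
#' the post-normalization variant class (`SNV` iff both alleles are single
#' bases).
#'
#' @param calls decomposed call table (see [decompose_calls()]).
#' @inheritParams normalize_variant
#' @return tibble with normalized `pos`, `ref`, `alt` plus `vclass` and
#'   `key` columns; `attr(, "normalized")` records whether a reference was
#'   used (`"left_aligned"`) or not (`"trim_only"`).
#' @export
normalize_calls <- function(calls, reference = NULL, window = 100) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) > 0) {
    norm <- pmap(list(calls$chrom, calls$pos, calls$ref, calls$alt),
                 function(c_, p_, r_, a_) {
                   normalize_variant(c_, p_, r_, a_, reference = reference,
                                     window = window)
                 })
    calls$pos <- map_int(norm, "pos")
    calls$ref <- map_chr(norm, "ref")
    calls$alt <- map_chr(norm, "alt")
  }
  calls$vclass <- variant_class(calls$ref, calls$alt)
  calls$key <- match_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  attr(calls, "normalized") <-
    if (is.null(reference)) "trim_only" else "left_aligned"
  calls
}

#' Build a normalized caller call-set from raw VCF records
#'
#' The full per-caller harmonization pipeline: caller-side FILTER gating,
#' multiallelic decomposition, trimming and left-alignment, and within-caller
#' deduplication of match keys (first occurrence wins, with a warning —
#' duplicates indicate upstream caller artifacts).
#'
#' @param calls raw call table from [read_caller_vcf()] (or any tibble with
#'   `chrom`, `pos`, `ref`, `alt`, `gt`, `caller` columns).
#' @param reference named character vector of chromosome sequences, or
#'   `NULL` for trim-only normalization.
#' @param caller_id optional override of the caller label.
#' @param keep_filtered admit records whose FILTER is neither `PASS` nor
#'   `.` (default `FALSE`: only caller-passing records enter voting).
#' @param window left-alignment window (bp).
#' @return normalized call-set tibble (class `covote_callset`): columns
#'   `chrom`, `pos`, `ref`, `alt`, `genotype`, `vclass`, `caller`, `key`,
#'   sorted by position.
#' @export
build_callset <- function(calls, reference = NULL, caller_id = NULL,
                          keep_filtered = FALSE, window = 100) {
  stopifnot(is.data.frame(calls))
  if (!is.null(caller_id)) calls$caller <- caller_id
  if (!"line" %in% names(calls)) calls$line <- seq_len(nrow(calls))
  if (!"filter" %in% names(calls)) calls$filter <- "PASS"
  if (!"gt" %in% names(calls) && "genotype" %in% names(calls)) {
    calls$gt <- gt_string(calls$genotype)
  }
  if (!keep_filtered) {
    calls <- filter(calls, is.na(.data$filter) | .data$filter %in% c("PASS", "."))
  }
  dec <- decompose_calls(calls)
  drp <- attr(dec, "dropped")
  if (!is.null(drp) && nrow(drp) > 0 &&
      any(drp$reason == "missing_genotype")) {
    warn(sprintf("caller '%s': %d record(s) with missing genotype excluded from voting",
                 calls$caller[1] %||% "?",
                 sum(drp$reason == "missing_genotype")))
  }
  norm <- normalize_calls(dec, reference = reference, window = window)
  dup <- duplicated(norm$key)
  if (any(dup)) {
    warn(sprintf("caller '%s': collapsed %d duplicate match key(s), keeping first occurrence",
                 norm$caller[1] %||% "?", sum(dup)))
    norm <- norm[!dup, ]
  }
  out <- sort_calls(select(norm, "chrom", "pos", "ref", "alt", "genotype",
                           "vclass", "caller", "key"))
  attr(out, "normalized") <- attr(norm, "normalized")
  class(out) <- c("covote_callset", class(out))
  out
}

# Guard used by the evaluation module: inputs must carry the trimmed
# invariant (no shared first+last base on multi-base allele pairs) and a key.
check_normalized <- function(calls, what = "calls") {
  if (!all(c("key", "genotype") %in% names(calls))) {
    covote_usage_error(
      "%s are not normalized: run build_callset()/normalize_calls() first",
      what)
  }
  if (nrow(calls) > 0) {
    r <- calls$ref; a <- calls$alt
    untrimmed <- nchar(r) > 1L & nchar(a) > 1L &
      substr(r, 1L, 1L) == substr(a, 1L, 1L) &
      substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))
    if (any(untrimmed)) {
      covote_usage_error("%s contain un-normalized alleles (e.g. %s)",
                         what, calls$key[which(untrimmed)[1]])
    }
  }
  invisible(calls)
}

#' Apply a variant to a reference sequence window
#'
#' Returns the sequence that results from substituting `alt` for `ref` at
#' `pos` (1-based within the chromosome) inside `window_seq`, which starts at
#' `window_start`. This is the semantic identity behind normalization: two
#' spellings are the same variant iff they produce the same edited sequence.
#'
#' @param window_seq reference subsequence.
#' @param window_start 1-based chromosome position of `window_seq[1]`.
#' @param pos,ref,alt the variant.
#' @return edited sequence string.
#' @export
apply_variant <- function(window_seq, window_start, pos, ref, alt) {
  off <- pos - window_start + 1L
  if (off < 1L || off + nchar(ref) - 1L > nchar(window_seq)) {
    covote_data_error("variant at %d does not fit in window [%d, %d]",
                      pos, window_start, window_start + nchar(window_seq) - 1L)
  }
  if (substr(window_seq, off, off + nchar(ref) - 1L) != ref) {
    covote_data_error("reference mismatch applying variant at %d", pos)
  }
  paste0(substr(window_seq, 1L, off - 1L), alt,
         substr(window_seq, off + nchar(ref), nchar(window_seq)))
}

# Right-shift / un-trim respellings used by the simulator to exercise
# harmonization: semantically identical alternative spellings of an indel.
respell_right <- function(chrom, pos, ref, alt, reference, max_steps = 50L) {
  chromseq <- reference[[chrom]]
  steps <- 0L
  repeat {
    n1 <- nchar(ref); n2 <- nchar(alt)
    if (steps >= max_steps) break
    if (n1 > 1L && n2 > 1L && substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2L, n1); alt <- substr(alt, 2L, n2); pos <- pos + 1L
      steps <- steps + 1L
    } else if ((n1 == 1L || n2 == 1L) && n1 != n2 &&
               substr(ref, 1, 1) == substr(alt, 1, 1)) {
      nxt <- pos + n1
      if (nxt > nchar(chromseq)) break
      b <- substr(chromseq, nxt, nxt)
      # exact mirror of one left-shift step: drop the shared anchor base,
      # append the next reference base; the left-shift step inverts it
      ref <- paste0(substr(ref, 2L, n1), b)
      alt <- paste0(substr(alt, 2L, n2), b)
      pos <- pos + 1L
      steps <- steps + 1L
    } else {
      break
    }
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

respell_untrim <- function(chrom, pos, ref, alt, reference) {
  chromseq <- reference[[chrom]]
  nxt <- pos + nchar(ref)
  if (nxt > nchar(chromseq)) return(list(pos = pos, ref = ref, alt = alt))
  b <- substr(chromseq, nxt, nxt)
  list(pos = as.integer(pos), ref = paste0(ref, b), alt = paste0(alt, b))
}
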