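# Independent oracles and fixture builders. Everything here is derived from
# first principles (per-site enumeration, per-base membership, string
# edits on character vectors) and deliberately shares no code with the
# package internals it checks.

# --- brute-force per-site voting oracle -------------------------------------

# Decides one site directly from the definition: stage 1 counts detecting
# callers; stage 2 compares het vs hom-alt tallies explicitly (the only two
# genotype classes), requiring a unique winner at or above the threshold.
oracle_vote_site <- function(genotypes, detection_min, concordance_min) {
  nm <- length(genotypes)
  n_het <- sum(genotypes == "het")
  n_hom <- sum(genotypes == "hom_alt")
  if (nm < detection_min) {
    g <- if (n_het > n_hom) "het" else if (n_hom > n_het) "hom_alt"
         else NA_character_
    return(list(status = "low_confidence", genotype = g, nm = nm))
  }
  if (n_het > n_hom && n_het >= concordance_min) {
    list(status = "consensus", genotype = "het", nm = nm)
  } else if (n_hom > n_het && n_hom >= concordance_min) {
    list(status = "consensus", genotype = "hom_alt", nm = nm)
  } else {
    list(status = "discordant", genotype = NA_character_, nm = nm)
  }
}

# A random voting instance: n_sites keys, each detected by a random
# non-empty caller subset with random genotypes. Returned as the bound
# tidy call table call_consensus() accepts.
random_instance <- function(n_callers, n_sites) {
  callers <- paste0("c", seq_len(n_callers))
  rows <- lapply(seq_len(n_sites), function(i) {
    det <- sample(callers, sample.int(n_callers, 1))
    tibble::tibble(
      chrom = "1", pos = 10L * i, ref = "A", alt = "G",
      genotype = sample(c("het", "hom_alt"), length(det), replace = TRUE),
      caller = det,
      key = sprintf("1:%d:A:G", 10L * i)
    )
  })
  dplyr::bind_rows(rows)
}

# Evaluate an instance with the oracle, returning a key-indexed data frame.
oracle_consensus <- function(instance, detection_min, concordance_min) {
  split_rows <- split(instance, instance$key)
  out <- lapply(split_rows, function(rows) {
    d <- oracle_vote_site(rows$genotype, detection_min, concordance_min)
    tibble::tibble(key = rows$key[1], status = d$status,
                   genotype = d$genotype, nm = d$nm)
  })
  dplyr::bind_rows(out)
}

# --- string-edit oracle ------------------------------------------------------

# Applies (pos, ref, alt) to a window by splicing character vectors; fails
# hard when ref does not match the window.
oracle_apply <- function(window_seq, window_start, pos, ref, alt) {
  v <- strsplit(window_seq, "")[[1]]
  off <- pos - window_start + 1L
  stopifnot(off >= 1L, off + nchar(ref) - 1L <= length(v))
  stopifnot(paste(v[off:(off + nchar(ref) - 1L)], collapse = "") == ref)
  head_v <- if (off > 1L) v[1:(off - 1L)] else character(0)
  tail_i <- off + nchar(ref)
  tail_v <- if (tail_i <= length(v)) v[tail_i:length(v)] else character(0)
  paste(c(head_v, strsplit(alt, "")[[1]], tail_v), collapse = "")
}

# --- brute-force region membership ------------------------------------------

# Per-base membership of raw (possibly overlapping) BED intervals on one
# chromosome of length L: base p (1-based) is inside iff start < p <= end
# for some raw interval.
oracle_membership <- function(starts, ends, L) {
  member <- rep(FALSE, L)
  for (i in seq_along(starts)) {
    lo <- starts[i] + 1L
    hi <- min(ends[i], L)
    if (lo <= hi) member[lo:hi] <- TRUE
  }
  member
}

# --- planted-repeat variant spellings ---------------------------------------

# Builds a window with an explicit tandem repeat (unit repeated k times)
# between random flanks, plus every equivalent spelling of a deletion or
# insertion of one unit, derived purely from the repeat structure: the same
# edit can be anchored before any unit boundary.
random_repeat_case <- function() {
  bases <- c("A", "C", "G", "T")
  unit_len <- sample(1:3, 1)
  unit <- paste(sample(bases, unit_len, replace = TRUE), collapse = "")
  k <- sample(3:6, 1)
  left <- paste(sample(bases, sample(8:15, 1), replace = TRUE), collapse = "")
  right <- paste(sample(bases, sample(8:15, 1), replace = TRUE), collapse = "")
  window <- paste0(left, strrep(unit, k), right)
  tract_start <- nchar(left) + 1L # 1-based window coordinate of the tract
  is_del <- runif(1) < 0.5
  # anchor base just before unit j (j = 0 .. k-1 for deletions, 0 .. k for
  # insertions); each spelling edits the same string
  n_anchor <- if (is_del) k else k + 1L
  spellings <- lapply(seq_len(n_anchor) - 1L, function(j) {
    pos <- tract_start + j * unit_len - 1L
    anchor <- substr(window, pos, pos)
    if (is_del) {
      list(pos = pos,
           ref = paste0(anchor, substr(window, pos + 1L, pos + unit_len)),
           alt = anchor)
    } else {
      list(pos = pos, ref = anchor, alt = paste0(anchor, unit))
    }
  })
  list(window = window, spellings = spellings, unit = unit, k = k,
       is_del = is_del)
}

# --- misc fixtures -----------------------------------------------------------

write_vcf_file <- function(body_lines, sample = "S1",
                           path = withr::local_tempfile(fileext = ".vcf",
                                                        .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gt, filter = "PASS", qual = ".") {
  paste(chrom, pos, ".", ref, alt, qual, filter, ".", "GT", gt, sep = "\t")
}

# Minimal normalized call table for evaluation fixtures.
calls_tbl <- function(pos, genotype, ref = "A", alt = "G", chrom = "1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    genotype = as.character(genotype),
    vclass = as.character(ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                                 "SNV", "INDEL")),
    key = paste(chrom, pos, ref, alt, sep = ":"))
}
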