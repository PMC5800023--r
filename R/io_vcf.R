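#' Read a single-sample VCF into a tidy call table
#'
#' Parses a plain or gzipped VCF v4.x with exactly one sample column and a
#' `GT` entry in FORMAT, one row per VCF record. Multiallelic records are kept
#' as-is (`alt` holds the comma-joined ALT field); decomposition happens in
#' [decompose_calls()]. Records with symbolic or breakend ALT alleles
#' (`<DEL>`, breakends, `*`) are skipped with a warning: the engine's scope is
#' SNVs and small indels. Records whose GT is missing (`./.`) are returned
#' with `gt = NA`.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param caller_id label identifying the source caller (default: file stem).
#' @param strip_chr strip a leading `"chr"` from chromosome labels so mixed
#'   dialects compare equal (default `TRUE`).
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter`, `info`, `gt`, `caller`, `line` (1-based line number in the
#'   file, for error tracing). The header lines are attached as
#'   `attr(, "meta")`.
#' @export
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
#' read_caller_vcf(vcf, caller_id = "gatk")
read_caller_vcf <- function(path, caller_id = NULL, strip_chr = TRUE) {
  if (!file.exists(path)) covote_data_error("VCF file not found: %s", path)
  caller_id <- caller_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  lines <- readr::read_lines(path)
  meta <- lines[startsWith(lines, "##")]
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L) {
    covote_data_error("%s: expected exactly one #CHROM header line", path)
  }
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) {
    covote_data_error(
      "%s: no sample column; single-sample VCF with GT required", path)
  }
  if (length(header) > 10L) {
    covote_data_error(
      "%s: %d sample columns found; single-sample VCF required",
      path, length(header) - 9L)
  }

  body_i <- setdiff(seq_along(lines), c(which(startsWith(lines, "#"))))
  body_i <- body_i[nzchar(trimws(lines[body_i]))]
  if (length(body_i) == 0L) {
    return(empty_call_table(caller_id, meta))
  }

  fields <- strsplit(lines[body_i], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    bad <- body_i[which(nf != 10L)[1]]
    covote_data_error("%s: malformed VCF line %d (%d fields, expected 10)",
                      path, bad, nf[which(nf != 10L)[1]])
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- body_i[which(is.na(pos) | pos < 1L)[1]]
    covote_data_error("%s: malformed VCF line %d (bad POS field)", path, bad)
  }

  out <- tibble(
    chrom = normalize_chrom(m[, 1], strip_chr),
    pos = pos,
    id = m[, 3],
    ref = m[, 4],
    alt = m[, 5],
    qual = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6]))),
    filter = m[, 7],
    info = m[, 8],
    gt = extract_gt(m[, 9], m[, 10], path, body_i),
    caller = caller_id,
    line = body_i
  )

  symbolic <- is_symbolic_alt(out$alt)
  if (any(symbolic)) {
    warn(sprintf("%s: skipped %d record(s) with symbolic/breakend ALT alleles",
                 path, sum(symbolic)))
    out <- out[!symbolic, ]
  }
  bad_allele <- !is_valid_allele(out$ref) |
    !map_lgl(strsplit(out$alt, ",", fixed = TRUE),
             function(a) all(is_valid_allele(a)))
  if (any(bad_allele)) {
    covote_data_error("%s: malformed VCF line %d (invalid allele characters)",
                      path, out$line[which(bad_allele)[1]])
  }
  attr(out, "meta") <- meta
  out
}

empty_call_table <- function(caller_id, meta = character()) {
  out <- tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alt = character(), qual = numeric(), filter = character(),
    info = character(), gt = character(), caller = character(),
    line = integer()
  )
  attr(out, "meta") <- meta
  out
}

# Pull the GT subfield out of FORMAT/sample columns; NA when absent or "./.".
extract_gt <- function(format, sample, path, line_no) {
  map_chr(seq_along(format), function(i) {
    keys <- strsplit(format[i], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", keys)
    if (is.na(gt_idx)) return(NA_character_)
    vals <- strsplit(sample[i], ":", fixed = TRUE)[[1]]
    if (length(vals) < gt_idx) {
      covote_data_error("%s: malformed VCF line %d (sample column shorter than FORMAT)",
                        path, line_no[i])
    }
    gt <- vals[gt_idx]
    pg <- parse_gt(gt)
    if (is.null(pg)) {
      covote_data_error("%s: malformed VCF line %d (unparseable GT '%s')",
                        path, line_no[i], gt)
    }
    if (pg$missing) NA_character_ else gt
  })
}

#' Write a consensus call-set as VCF 4.2
#'
#' Serializes voted records with the per-variant support annotations in INFO:
#' `NM` (number of methods detecting the site), `CALLERS` (comma-joined
#' caller labels that detected it) and `STATUS`
#' (`consensus|low_confidence|discordant`). The single sample column carries
#' the winning genotype as GT (`./.` for discordant sites, which have no
#' winning genotype). Output round-trips through [read_consensus_vcf()].
#'
#' @param records tibble of voted records as produced by [call_consensus()]
#'   (columns `chrom`, `pos`, `ref`, `alt`, `genotype`, `status`, `nm`,
#'   `detectors`), sorted by (chrom, pos, ref, alt).
#' @param path output path.
#' @param sample_name sample column label (default `"SAMPLE"`).
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(records, path, sample_name = "SAMPLE") {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    o <- order(records$chrom, records$pos, records$ref, records$alt)
    if (!identical(o, seq_len(nrow(records)))) {
      covote_usage_error(
        "records must be sorted by (chrom, pos, ref, alt); sort before writing")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=covote",
    "##INFO=<ID=NM,Number=1,Type=Integer,Description=\"Number of methods detecting the variant\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers detecting the variant\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Voting status: consensus, low_confidence or discordant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(records) > 0) {
    info <- sprintf("NM=%d;CALLERS=%s;STATUS=%s",
                    records$nm, records$detectors, records$status)
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  ".", ".", info, "GT", gt_string(records$genotype),
                  sep = "\t")
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a covote consensus VCF back into a voted-record table
#'
#' Inverse of [write_consensus_vcf()]: parses the `NM`, `CALLERS` and
#' `STATUS` INFO keys back into columns.
#'
#' @inheritParams read_caller_vcf
#' @return tibble with columns `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `status`, `nm`, `detectors`, `key`.
#' @export
read_consensus_vcf <- function(path, strip_chr = TRUE) {
  raw <- read_caller_vcf(path, caller_id = "consensus", strip_chr = strip_chr)
  info_field <- function(info, key) {
    pairs <- strsplit(info, ";", fixed = TRUE)[[1]]
    hit <- pairs[startsWith(pairs, paste0(key, "="))]
    if (length(hit) == 0L) NA_character_ else sub("^[^=]+=", "", hit[1])
  }
  nm <- suppressWarnings(as.integer(
    vapply(raw$info, info_field, "", key = "NM", USE.NAMES = FALSE)))
  status <- vapply(raw$info, info_field, "", key = "STATUS", USE.NAMES = FALSE)
  detectors <- vapply(raw$info, info_field, "", key = "CALLERS", USE.NAMES = FALSE)
  genotype <- map_chr(raw$gt, function(g) {
    if (is.na(g)) return(NA_character_)
    pg <- parse_gt(g)
    genotype_class(pg$a, pg$b)
  })
  tibble(
    chrom = raw$chrom, pos = raw$pos, ref = raw$ref, alt = raw$alt,
    genotype = genotype, status = status, nm = nm, detectors = detectors,
    key = match_key(raw$chrom, raw$pos, raw$ref, raw$alt)
  )
}

#' Write a plain single-sample VCF from a call table
#'
#' Serializes raw or normalized calls (e.g. simulated caller output from
#' [simulate_caller()], or a truth set) as a minimal VCF 4.2 with a GT-only
#' sample column.
#'
#' @param calls tibble with `chrom`, `pos`, `ref`, `alt` and either `gt`
#'   (raw GT strings) or `genotype` (`"het"`/`"hom_alt"`).
#' @param path output path.
#' @param sample_name sample column label.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_name = "SAMPLE") {
  stopifnot(is.data.frame(calls))
  calls <- sort_calls(calls)
  gt <- if ("gt" %in% names(calls)) {
    ifelse(is.na(calls$gt), "./.", calls$gt)
  } else {
    gt_string(calls$genotype)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=covote",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  ".", "PASS", ".", "GT", gt, sep = "\t")
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Export a call or evaluation table as TSV
#'
#' Fixed-column-order TSV export of a consensus call table
#' (`chrom, pos, ref, alt, genotype, status, nm, callers`).
#'
#' @param records voted records (see [call_consensus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_consensus_tsv <- function(records, path) {
  out <- tibble(
    chrom = records$chrom, pos = records$pos, ref = records$ref,
    alt = records$alt, genotype = records$genotype, status = records$status,
    nm = records$nm, callers = records$detectors
  )
  readr::write_tsv(out, path)
  invisible(path)
}
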