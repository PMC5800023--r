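# Region sets: 0-based half-open intervals used for evaluable-region
# restriction and depth stratification. Internally a plain tibble
# (chrom, start, end) with a "label" attribute; merging goes through
# IRanges::reduce so overlap semantics match the rest of the genomics stack.

#' Construct a region set
#'
#' Builds a set of genomic intervals in BED convention (0-based, half-open).
#' Overlapping and bookended (adjacent) intervals on the same chromosome are
#' merged, and intervals are returned sorted, so membership queries are
#' unambiguous.
#'
#' @param chrom,start,end parallel vectors of intervals; `start < end`
#'   (0-based half-open).
#' @param label stratum name carried through evaluation output
#'   (e.g. `"depth>=10"`).
#' @param strip_chr strip a leading `"chr"` from chromosome labels.
#' @return A tibble of class `covote_regions` with columns
#'   `chrom`, `start`, `end`, sorted and non-overlapping.
#' @export
#' @examples
#' region_set(c("1", "1"), c(0, 50), c(100, 150), label = "target")
region_set <- function(chrom, start, end, label = "regions", strip_chr = TRUE) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyNA(start) || anyNA(end)) {
    covote_data_error("region coordinates must be numeric")
  }
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    covote_data_error("empty or inverted interval %s:%s-%s (end must exceed start)",
                      chrom[i], start[i], end[i])
  }
  chrom <- normalize_chrom(as.character(chrom), strip_chr)
  if (length(chrom) == 0L) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    # BED half-open -> IRanges closed 1-based; reduce() merges overlaps and,
    # with min.gapwidth = 1, bookended neighbours as well.
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    gr <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    gr <- GenomicRanges::sort(gr)
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = as.numeric(GenomicRanges::start(gr)) - 1,
      end = as.numeric(GenomicRanges::end(gr))
    )
  }
  structure(out, label = label, class = c("covote_regions", class(out)))
}

#' Read a BED file into a region set
#'
#' Accepts BED3 or wider (columns beyond the third are ignored), merges
#' overlapping/adjacent intervals, and validates every line: non-numeric
#' coordinates or `end <= start` are errors naming the offending line.
#'
#' @param path path to a BED file (plain or gzipped).
#' @inheritParams region_set
#' @return a `covote_regions` tibble.
#' @export
read_bed_regions <- function(path, label = NULL, strip_chr = TRUE) {
  if (!file.exists(path)) covote_data_error("BED file not found: %s", path)
  label <- label %||% sub("\\.bed(\\.gz)?$", "", basename(path))
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) &
    !startsWith(lines, "#") & !startsWith(lines, "track") &
    !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(region_set(character(), numeric(), numeric(), label = label))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- lengths(fields) < 3L
  if (any(short)) {
    covote_data_error("%s: line %d has fewer than 3 columns",
                      path, lineno[which(short)[1]])
  }
  chrom <- map_chr(fields, 1)
  start <- suppressWarnings(as.numeric(map_chr(fields, 2)))
  end <- suppressWarnings(as.numeric(map_chr(fields, 3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    covote_data_error("%s: line %d has non-numeric coordinates",
                      path, lineno[which(bad)[1]])
  }
  if (any(end <= start)) {
    covote_data_error("%s: line %d has end <= start",
                      path, lineno[which(end <= start)[1]])
  }
  region_set(chrom, start, end, label = label, strip_chr = strip_chr)
}

#' Write a region set as BED3
#'
#' @param regions a `covote_regions` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_regions <- function(regions, path) {
  readr::write_tsv(
    tibble(chrom = regions$chrom,
           start = format(regions$start, scientific = FALSE, trim = TRUE),
           end = format(regions$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE)
  invisible(path)
}

#' Test which variant positions fall inside a region set
#'
#' A variant is assigned by its 1-based anchor position: it is inside a
#' BED interval `[start, end)` iff `start < pos <= end`.
#'
#' @param chrom,pos vectors of 1-based variant anchor positions.
#' @param regions a `covote_regions` tibble (or `NULL`, meaning everywhere).
#' @return logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  if (nrow(regions) == 0L || length(pos) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  IRanges::overlapsAny(q, s)
}

region_label <- function(regions) {
  attr(regions, "label") %||% "regions"
}

#' @export
print.covote_regions <- function(x, ...) {
  cat(sprintf("<region set '%s': %d interval(s), %s bp>\n",
              region_label(x), nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  NextMethod()
}
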