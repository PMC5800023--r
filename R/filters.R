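# Prioritization filters over an annotated variant table. The table is one
# row per normalized variant with the support column NM, the variant class,
# a functional class from an external annotator (vocabulary not validated
# here), an optional minor allele frequency, optional gene symbol, optional
# caller labels, and one `db_<name>` column per variation database holding
# the accession or NA. All criteria of a filter specification are combined
# by conjunction; filtering is contractive, idempotent and order-independent.

#' Build a filter specification
#'
#' Any subset of criteria may be set; unset criteria do not constrain. At
#' most one of `nm_min` / `nm_exact` may be given, and a database may not be
#' required both present and absent.
#'
#' @param nm_min keep variants supported by at least this many methods.
#' @param nm_exact keep variants supported by exactly this many methods.
#' @param required_callers caller labels that must all appear among the
#'   variant's supporting callers.
#' @param functional_classes allowed functional classes (e.g. `"exonic"`,
#'   `"splicing"`).
#' @param maf_max maximum minor allele frequency. Variants with no recorded
#'   MAF pass by default — absence from the frequency database is evidence
#'   of rarity, the situation of interest in rare-disease prioritization —
#'   unless `keep_missing_maf = FALSE`.
#' @param vclass `"SNV"` or `"INDEL"`.
#' @param in_database,not_in_database database names (matching `db_<name>`
#'   table columns) in which the variant must / must not have an accession.
#' @param genes allowed gene symbols.
#' @param region a `covote_regions` set the variant position must fall in.
#' @param keep_missing_maf see `maf_max`.
#' @return list of class `covote_filter_spec`.
#' @export
#' @examples
#' filter_spec(nm_min = 2, maf_max = 0.01, functional_classes = "exonic")
filter_spec <- function(nm_min = NULL, nm_exact = NULL,
                        required_callers = NULL, functional_classes = NULL,
                        maf_max = NULL, vclass = NULL,
                        in_database = NULL, not_in_database = NULL,
                        genes = NULL, region = NULL,
                        keep_missing_maf = TRUE) {
  if (!is.null(nm_min) && !is.null(nm_exact)) {
    covote_usage_error("set at most one of nm_min and nm_exact")
  }
  both <- intersect(in_database, not_in_database)
  if (length(both) > 0) {
    covote_usage_error(
      "database '%s' required both present and absent", both[1])
  }
  if (!is.null(vclass) && !all(vclass %in% c("SNV", "INDEL"))) {
    covote_usage_error("vclass must be 'SNV' or 'INDEL'")
  }
  structure(list(
    nm_min = nm_min, nm_exact = nm_exact,
    required_callers = required_callers,
    functional_classes = functional_classes,
    maf_max = maf_max, vclass = vclass,
    in_database = in_database, not_in_database = not_in_database,
    genes = genes, region = region, keep_missing_maf = keep_missing_maf
  ), class = "covote_filter_spec")
}

db_columns <- function(variants) {
  sub("^db_", "", grep("^db_", names(variants), value = TRUE))
}

#' Apply a filter specification to an annotated variant table
#'
#' Keeps the rows satisfying every criterion of `spec` (conjunction); row
#' order is preserved. Referencing a database absent from the table is an
#' error listing the known database names.
#'
#' @param variants annotated variant tibble: columns `chrom`, `pos`, `ref`,
#'   `alt`, `nm`, `vclass`, and optionally `functional_class`, `maf`,
#'   `gene`, `callers`, `db_<name>` columns.
#' @param spec a [filter_spec()] (or arguments forwarded to it via `...`).
#' @param ... convenience: criteria passed directly instead of `spec`.
#' @return the filtered tibble (subset of the input rows, original order).
#' @export
#' @examples
#' tbl <- tibble::tibble(chrom = "1", pos = 1:3, ref = "A", alt = "G",
#'                       nm = c(1, 2, 3), vclass = "SNV")
#' apply_filters(tbl, nm_min = 2)
apply_filters <- function(variants, spec = NULL, ...) {
  stopifnot(is.data.frame(variants))
  if (is.null(spec)) spec <- filter_spec(...)
  if (!inherits(spec, "covote_filter_spec")) {
    covote_usage_error("spec must be created by filter_spec()")
  }
  keep <- rep(TRUE, nrow(variants))
  need <- function(col) {
    if (!col %in% names(variants)) {
      covote_usage_error("filter needs column '%s', absent from the table", col)
    }
    variants[[col]]
  }
  if (!is.null(spec$nm_min)) keep <- keep & need("nm") >= spec$nm_min
  if (!is.null(spec$nm_exact)) keep <- keep & need("nm") == spec$nm_exact
  if (!is.null(spec$required_callers)) {
    sets <- str_split(need("callers"), ",")
    keep <- keep & map_lgl(sets, ~all(spec$required_callers %in% .x))
  }
  if (!is.null(spec$functional_classes)) {
    keep <- keep & need("functional_class") %in% spec$functional_classes
  }
  if (!is.null(spec$maf_max)) {
    maf <- need("maf")
    keep <- keep & if_else(is.na(maf), spec$keep_missing_maf,
                           maf <= spec$maf_max)
  }
  if (!is.null(spec$vclass)) keep <- keep & need("vclass") %in% spec$vclass
  for (db in c(spec$in_database, spec$not_in_database)) {
    col <- paste0("db_", db)
    if (!col %in% names(variants)) {
      known <- db_columns(variants)
      covote_usage_error(
        "unknown database '%s'; known databases: %s", db,
        if (length(known)) paste(known, collapse = ", ") else "(none)")
    }
  }
  for (db in spec$in_database) {
    keep <- keep & !is.na(variants[[paste0("db_", db)]])
  }
  for (db in spec$not_in_database) {
    keep <- keep & is.na(variants[[paste0("db_", db)]])
  }
  if (!is.null(spec$genes)) keep <- keep & need("gene") %in% spec$genes
  if (!is.null(spec$region)) {
    keep <- keep & in_regions(variants$chrom, variants$pos, spec$region)
  }
  variants[keep, ]
}

#' Write an annotated variant table
#'
#' Lossless TSV (or CSV) export with a fixed leading column order; extra
#' columns (e.g. `db_*`) follow in their table order.
#'
#' @param variants annotated variant tibble.
#' @param path output path.
#' @param format `"tsv"` (lossless round-trip) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  lead <- intersect(c("chrom", "pos", "ref", "alt", "genotype", "nm",
                      "vclass", "functional_class", "maf", "gene", "callers"),
                    names(variants))
  out <- relocate(variants, dplyr::all_of(lead))
  if (format == "tsv") readr::write_tsv(out, path)
  else readr::write_csv(out, path)
  invisible(path)
}

#' Read an annotated variant table
#'
#' @param path TSV (or CSV) written by [write_variant_table()] or following
#'   its documented header.
#' @param format `"tsv"` or `"csv"`.
#' @return tibble; `chrom`, `ref`, `alt` and `db_*` columns as character,
#'   `pos`/`nm` integer, `maf` double.
#' @export
read_variant_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE,
                col_types = readr::cols(
                  chrom = readr::col_character(),
                  ref = readr::col_character(),
                  alt = readr::col_character(),
                  .default = readr::col_guess()))
  if ("pos" %in% names(tbl)) tbl$pos <- as.integer(tbl$pos)
  if ("nm" %in% names(tbl)) tbl$nm <- as.integer(tbl$nm)
  for (col in grep("^db_", names(tbl), value = TRUE)) {
    tbl[[col]] <- as.character(tbl[[col]])
  }
  if ("gene" %in% names(tbl)) tbl$gene <- as.character(tbl$gene)
  if ("functional_class" %in% names(tbl)) {
    tbl$functional_class <- as.character(tbl$functional_class)
  }
  tbl
}
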