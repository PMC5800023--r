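# Genotype-exact benchmarking against a truth set. A call is a true
# positive only when both its match key (chrom, pos, ref, alt after
# normalization) and its unordered diploid genotype agree with the truth
# set — anything less is wrong. A call whose key matches truth but whose
# genotype differs counts as one false positive AND leaves the truth
# variant un-recovered (one false negative): the variant was not correctly
# genotyped and the emitted call is incorrect.
#
# "Specificity" here is precision, TP / (TP + FP): true negatives are
# ill-defined genome-wide, and precision is the standard surrogate in
# variant-calling benchmarks. All metrics can be restricted to evaluable
# regions (e.g. depth >= 10) and stratified over depth intervals; variants
# are assigned to a stratum by the 1-based anchor position of their
# normalized spelling.

#' Evaluate a call-set against a truth set
#'
#' Genotype-exact confusion counts and derived sensitivity / specificity
#' (precision), per variant class (SNV, INDEL) and overall (ALL), optionally
#' restricted to evaluable regions. Calls and truth must both be normalized
#' (same reference, same settings): un-normalized alleles are rejected.
#'
#' @param calls normalized calls to score: a `covote_callset`, a
#'   `covote_consensus` table (only its `consensus` stratum is scored, the
#'   low-confidence and discordant side-sets being reported separately by
#'   design), or any tibble with `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `key`.
#' @param truth normalized truth call-set (same columns).
#' @param regions optional `covote_regions` evaluable-region set; calls and
#'   truth outside it are excluded from all counts.
#' @param stratum label stored in the output (defaults to the region set's
#'   label, or `"ALL"`).
#' @return tibble of class `covote_eval` with columns `stratum`, `vclass`
#'   (`"SNV"`, `"INDEL"`, `"ALL"`), `tp`, `fp`, `fn`, `sensitivity`
#'   (`tp/(tp+fn)`), `specificity` (`tp/(tp+fp)`; `NA` when the denominator
#'   is 0). Per-variant verdicts (TP, FP_novel, FP_genotype, FN) are
#'   attached as `attr(, "detail")`.
#' @export
evaluate_calls <- function(calls, truth, regions = NULL, stratum = NULL) {
  if (inherits(calls, "covote_consensus")) {
    calls <- consensus_stratum(calls, "consensus")
  }
  calls <- as_tibble(calls)
  truth <- as_tibble(truth)
  check_normalized(calls, "calls")
  check_normalized(truth, "truth set")
  stratum <- stratum %||%
    (if (is.null(regions)) "ALL" else region_label(regions))

  if (!is.null(regions)) {
    calls <- calls[in_regions(calls$chrom, calls$pos, regions), ]
    truth <- truth[in_regions(truth$chrom, truth$pos, regions), ]
  }
  if (!"vclass" %in% names(calls)) calls$vclass <- variant_class(calls$ref, calls$alt)
  if (!"vclass" %in% names(truth)) truth$vclass <- variant_class(truth$ref, truth$alt)

  truth_gt <- truth$genotype[match(calls$key, truth$key)]
  call_verdict <- dplyr::case_when(
    is.na(truth_gt) ~ "FP_novel",
    truth_gt == calls$genotype ~ "TP",
    .default = "FP_genotype"
  )
  recovered <- calls$key[call_verdict == "TP"]
  truth_verdict <- if_else(truth$key %in% recovered, "TP", "FN")

  detail <- bind_rows(
    tibble(role = "call", key = calls$key, vclass = calls$vclass,
           genotype = calls$genotype, verdict = call_verdict),
    tibble(role = "truth", key = truth$key, vclass = truth$vclass,
           genotype = truth$genotype, verdict = truth_verdict)
  )

  count_class <- function(vc) {
    ci <- if (vc == "ALL") rep(TRUE, nrow(calls)) else calls$vclass == vc
    ti <- if (vc == "ALL") rep(TRUE, nrow(truth)) else truth$vclass == vc
    tp <- sum(call_verdict[ci] == "TP")
    fp <- sum(call_verdict[ci] != "TP")
    fn <- sum(truth_verdict[ti] == "FN")
    tibble(stratum = stratum, vclass = vc, tp = tp, fp = fp, fn = fn,
           sensitivity = if ((tp + fn) > 0) tp / (tp + fn) else NA_real_,
           specificity = if ((tp + fp) > 0) tp / (tp + fp) else NA_real_)
  }
  out <- bind_rows(lapply(c("SNV", "INDEL", "ALL"), count_class))
  structure(out, detail = detail, class = c("covote_eval", class(out)))
}

#' Stratified evaluation over depth (or any) region strata
#'
#' Runs [evaluate_calls()] once per stratum; strata may overlap and each is
#' evaluated independently. When the strata partition the evaluable space,
#' per-stratum TP/FP/FN are additive.
#'
#' @inheritParams evaluate_calls
#' @param strata a non-empty named list of `covote_regions` (names override
#'   region labels), e.g. `list("depth<30" = shallow, "depth>=30" = deep)`.
#' @return a `covote_eval` tibble with one block of rows per stratum.
#' @export
stratify_evaluation <- function(calls, truth, strata) {
  if (!is.list(strata) || length(strata) == 0L ||
      inherits(strata, "covote_regions")) {
    covote_usage_error("strata must be a non-empty list of region sets")
  }
  labels <- names(strata) %||% map_chr(strata, region_label)
  if (is.null(names(strata))) names(strata) <- labels
  res <- imap(strata, function(rg, nm) {
    evaluate_calls(calls, truth, regions = rg, stratum = nm)
  })
  details <- map(res, ~attr(.x, "detail"))
  out <- bind_rows(lapply(res, as_tibble))
  structure(out, detail = bind_rows(details, .id = "stratum"),
            class = c("covote_eval", class(out)))
}

#' Per-variant confusion detail behind an evaluation
#'
#' @param x a `covote_eval` result.
#' @return tibble of per-call and per-truth-variant verdicts:
#'   `TP`, `FP_novel` (key absent from truth), `FP_genotype` (key present,
#'   genotype mismatch), `FN`.
#' @export
confusion_detail <- function(x) {
  attr(x, "detail")
}

#' @method tidy covote_eval
#' @export
tidy.covote_eval <- function(x, ...) {
  as_tibble(x)
}

#' @method glance covote_eval
#' @export
glance.covote_eval <- function(x, ...) {
  all_rows <- as_tibble(x)[x$vclass == "ALL", ]
  summarise(all_rows,
            n_strata = dplyr::n(),
            tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
            sensitivity = if (sum(.data$tp + .data$fn) > 0)
              sum(.data$tp) / sum(.data$tp + .data$fn) else NA_real_,
            specificity = if (sum(.data$tp + .data$fp) > 0)
              sum(.data$tp) / sum(.data$tp + .data$fp) else NA_real_)
}

#' Plot sensitivity and specificity per stratum and variant class
#'
#' @param object a `covote_eval` result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot covote_eval
#' @export
autoplot.covote_eval <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$stratum, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~.data$vclass) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}

#' Export an evaluation report as TSV
#'
#' Columns: stratum, vclass, tp, fp, fn, sensitivity, specificity.
#'
#' @param x a `covote_eval` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_eval_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
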