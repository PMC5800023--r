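# The two-stage voting engine. Stage 1 (detection): a site must be called by
# at least detection_min of the n callers; sites below the threshold are the
# low-confidence call-set (with the default 2-of-3 majority these are the
# single-tool calls). Stage 2 (genotype concordance): among detected sites,
# the unique most frequent genotype must be shared by at least
# concordance_min callers; otherwise the site is discordant. All callers
# count equally and phase is ignored — concordance is on the unordered
# diploid genotype (het vs hom-alt).

#' Voting parameters for the two-stage consensus
#'
#' @param n_callers number of input call-sets.
#' @param detection_min minimum callers detecting a site (stage 1).
#' @param concordance_min minimum callers sharing the winning genotype
#'   (stage 2).
#' @return list of class `voting_params`. Defaults implement the simple
#'   majority 2-of-3 rule; `voting_params(4, 4, 4)` is the strict
#'   all-methods consensus.
#' @export
voting_params <- function(n_callers = 3L, detection_min = 2L,
                          concordance_min = 2L) {
  n_callers <- as.integer(n_callers)
  detection_min <- as.integer(detection_min)
  concordance_min <- as.integer(concordance_min)
  if (is.na(n_callers) || n_callers < 1L) {
    covote_usage_error("n_callers must be a positive integer")
  }
  if (!(1L <= concordance_min && concordance_min <= detection_min &&
        detection_min <= n_callers)) {
    covote_usage_error(
      "need 1 <= concordance_min (%d) <= detection_min (%d) <= n_callers (%d)",
      concordance_min, detection_min, n_callers)
  }
  structure(list(n_callers = n_callers, detection_min = detection_min,
                 concordance_min = concordance_min),
            class = "voting_params")
}

# Decide one site given genotype counts; shared by vote_site and
# call_consensus. Returns list(status, genotype, supporters).
decide_site <- function(genotypes, callers, params) {
  nm <- length(genotypes)
  tallies <- table(genotypes)
  top <- max(tallies)
  winners <- names(tallies)[tallies == top]
  if (nm < params$detection_min) {
    status <- "low_confidence"
    genotype <- if (length(winners) == 1L) winners else NA_character_
    supporters <- if (length(winners) == 1L) callers[genotypes == winners] else character()
  } else if (length(winners) == 1L && top >= params$concordance_min) {
    status <- "consensus"
    genotype <- winners
    supporters <- callers[genotypes == winners]
  } else {
    # ties at or above the threshold, or no genotype reaching it
    status <- "discordant"
    genotype <- NA_character_
    supporters <- character()
  }
  list(status = status, genotype = genotype,
       supporters = paste(sort(supporters), collapse = ","))
}

#' Vote a single site
#'
#' Applies the two-stage scheme to the genotype calls observed at one match
#' key. Exposed mainly for inspection and testing; [call_consensus()] is the
#' call-set-level entry point.
#'
#' @param genotypes named character vector, caller label -> genotype class
#'   (`"het"` or `"hom_alt"`); missing genotypes must be removed upstream.
#' @param params a [voting_params()] object.
#' @return one-row tibble: `status`, `genotype`, `nm`, `supporters`,
#'   `detectors` (comma-joined, sorted caller labels).
#' @export
#' @examples
#' vote_site(c(gatk = "het", varscan = "het", freebayes = "hom_alt"))
vote_site <- function(genotypes, params = voting_params()) {
  if (length(genotypes) == 0L) {
    covote_usage_error("vote_site() requires at least one genotype call")
  }
  if (is.null(names(genotypes)) || anyDuplicated(names(genotypes))) {
    covote_usage_error("genotypes must be named by distinct caller labels")
  }
  if (length(genotypes) > params$n_callers) {
    covote_usage_error("%d calls at one site exceeds n_callers = %d",
                       length(genotypes), params$n_callers)
  }
  if (anyNA(genotypes)) {
    covote_usage_error("missing genotypes must be removed before voting")
  }
  d <- decide_site(unname(genotypes), names(genotypes), params)
  tibble(status = d$status, genotype = d$genotype,
         nm = length(genotypes), supporters = d$supporters,
         detectors = paste(sort(names(genotypes)), collapse = ","))
}

#' Vote all sites of a set of harmonized call-sets
#'
#' Partitions the union of match keys across callers into consensus,
#' low-confidence and discordant records by the two-stage voting scheme. The
#' result is invariant to the order of call-sets and of records within them.
#'
#' @param calls either a list of normalized call-sets (from
#'   [build_callset()]) or a single tibble with a `caller` column binding
#'   them; required columns `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `caller`, `key` (plus `vclass`).
#' @param params a [voting_params()] object; `n_callers` must equal the
#'   number of distinct caller labels.
#' @return tibble of class `covote_consensus`, one row per match key, sorted
#'   by (chrom, pos, ref, alt): columns `chrom`, `pos`, `ref`, `alt`,
#'   `vclass`, `genotype`, `status`, `nm` (number of detecting methods),
#'   `supporters`, `detectors`, `key`. The voting parameters are attached
#'   as `attr(, "params")`.
#' @export
call_consensus <- function(calls, params = voting_params()) {
  if (is.data.frame(calls)) {
    tbl <- as_tibble(calls)
  } else {
    tbl <- bind_rows(lapply(calls, as_tibble))
  }
  if (nrow(tbl) == 0L && !"caller" %in% names(tbl)) tbl$caller <- character()
  labels <- unique(tbl$caller)
  if (!is.data.frame(calls)) {
    input_labels <- map_chr(calls, function(x) {
      u <- unique(x$caller)
      if (length(u) > 1L) covote_usage_error("a call-set mixes caller labels")
      if (length(u) == 0L) NA_character_ else u
    })
    input_labels <- input_labels[!is.na(input_labels)]
    if (length(calls) != params$n_callers) {
      covote_usage_error("%d call-sets supplied but n_callers = %d",
                         length(calls), params$n_callers)
    }
    if (anyDuplicated(input_labels)) {
      covote_usage_error("duplicate caller labels across call-sets")
    }
  } else if (length(labels) > params$n_callers) {
    covote_usage_error("%d distinct callers in input but n_callers = %d",
                       length(labels), params$n_callers)
  }
  if (!"vclass" %in% names(tbl)) {
    tbl$vclass <- variant_class(tbl$ref, tbl$alt)
  }
  if (!"key" %in% names(tbl)) {
    tbl$key <- match_key(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
  }
  na_gt <- is.na(tbl$genotype)
  if (any(na_gt)) {
    warn(sprintf("%d call(s) with missing genotype excluded from voting",
                 sum(na_gt)))
    tbl <- tbl[!na_gt, ]
  }
  dup <- duplicated(tbl[, c("caller", "key")])
  if (any(dup)) {
    warn(sprintf("collapsed %d within-caller duplicate key(s) before voting",
                 sum(dup)))
    tbl <- tbl[!dup, ]
  }

  if (nrow(tbl) == 0L) {
    empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), vclass = character(),
                    genotype = character(), status = character(),
                    nm = integer(), supporters = character(),
                    detectors = character(), key = character())
    return(structure(empty, params = params,
                     class = c("covote_consensus", class(empty))))
  }

  voted <- tbl |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$vclass,
             .data$key) |>
    summarise(
      nm = dplyr::n(),
      decision = list(decide_site(.data$genotype, .data$caller, params)),
      detectors = paste(sort(.data$caller), collapse = ","),
      .groups = "drop"
    ) |>
    mutate(
      status = map_chr(.data$decision, "status"),
      genotype = map_chr(.data$decision, "genotype"),
      supporters = map_chr(.data$decision, "supporters")
    ) |>
    select("chrom", "pos", "ref", "alt", "vclass", "genotype", "status",
           "nm", "supporters", "detectors", "key") |>
    sort_calls()

  structure(voted, params = params,
            class = c("covote_consensus", class(voted)))
}

#' Extract one stratum of a voted call-set
#'
#' @param voted a `covote_consensus` table from [call_consensus()].
#' @param status one of `"consensus"`, `"low_confidence"`, `"discordant"`.
#' @return tibble of the records with that status.
#' @export
consensus_stratum <- function(voted, status = c("consensus", "low_confidence",
                                                "discordant")) {
  status <- match.arg(status)
  as_tibble(voted)[voted$status == status, ]
}

#' @export
print.covote_consensus <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<consensus call-set: %d site(s); %d-of-%d detection, %d-of-%d concordance>\n",
              nrow(x), p$detection_min, p$n_callers, p$concordance_min,
              p$n_callers))
  print(table(factor(x$status,
                     c("consensus", "low_confidence", "discordant"))))
  invisible(x)
}

#' Tidy a voted call-set
#'
#' @param x a `covote_consensus` object.
#' @param ... unused.
#' @return the underlying tibble, one row per voted site.
#' @method tidy covote_consensus
#' @export
tidy.covote_consensus <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a voted call-set
#'
#' @param x a `covote_consensus` object.
#' @param ... unused.
#' @return tibble with the voting parameters and the size of each output
#'   stratum.
#' @method glance covote_consensus
#' @export
glance.covote_consensus <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_callers = p$n_callers,
    detection_min = p$detection_min,
    concordance_min = p$concordance_min,
    n_sites = nrow(x),
    n_consensus = sum(x$status == "consensus"),
    n_low_confidence = sum(x$status == "low_confidence"),
    n_discordant = sum(x$status == "discordant")
  )
}

#' Plot the composition of a voted call-set
#'
#' Bar chart of consensus / low-confidence / discordant counts, split by
#' variant class and by NM.
#'
#' @param object a `covote_consensus` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot covote_consensus
#' @export
autoplot.covote_consensus <- function(object, ...) {
  df <- as_tibble(object) |>
    count(.data$status, .data$vclass, .data$nm)
  ggplot(df, aes(x = factor(.data$nm), y = .data$n, fill = .data$status)) +
    geom_col(position = "stack") +
    facet_wrap(~.data$vclass) +
    labs(x = "NM (methods detecting the site)", y = "sites",
         fill = "voting status") +
    theme_minimal()
}

#' Expected consensus sensitivity under independent callers
#'
#' Closed-form detection probability of an m-of-n consensus when each of n
#' independent callers detects a true variant with probability `s`:
#' the binomial tail \eqn{\sum_{j \ge m} \binom{n}{j} s^j (1-s)^{n-j}}.
#' With the default 2-of-3 majority this is \eqn{3 s^2 (1-s) + s^3}.
#'
#' @param s per-caller sensitivity.
#' @param n_callers number of callers.
#' @param detection_min consensus detection threshold.
#' @return expected consensus sensitivity.
#' @export
#' @examples
#' expected_consensus_sensitivity(0.9) # 0.972
expected_consensus_sensitivity <- function(s, n_callers = 3, detection_min = 2) {
  stats::pbinom(detection_min - 1, n_callers, s, lower.tail = FALSE)
}
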