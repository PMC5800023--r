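# Synthetic truth sets and callers. The simulator emulates N independent
# variant callers observing one shared truth set: each caller detects a true
# variant with its own sensitivity (optionally modulated per depth stratum),
# mis-genotypes a detected variant (het <-> hom-alt) with a genotype-error
# probability, and adds false calls at a per-megabase rate at positions
# disjoint from the truth set. A fraction of emitted indels is re-spelled in
# a semantically equivalent but non-normalized form (right-shifted or
# un-trimmed) so that the harmonization stage is actually exercised. The
# synthetic genome carries planted homopolymer and dinucleotide repeats —
# left-alignment is only observable in repetitive context.
#
# Because callers are independent given truth, consensus accuracy has exact
# closed forms (see expected_consensus_sensitivity()), which the test-suite
# and acceptance protocol compare against simulation.

#' Simulate a reference chromosome with planted repeats
#'
#' Random A/C/G/T sequence interspersed with homopolymer runs (6–12 bp) and
#' dinucleotide repeats (4–8 units) roughly every `repeat_every` bases.
#'
#' @param length chromosome length in bp.
#' @param chrom chromosome label.
#' @param seed RNG seed (restored on exit).
#' @param repeat_every mean spacing between planted repeat tracts.
#' @return named character vector of length one (the chromosome).
#' @export
simulate_genome <- function(length = 1e5, chrom = "1", seed = NULL,
                            repeat_every = 250) {
  if (!is.null(seed)) withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  chunks <- character(0)
  total <- 0L
  while (total < length) {
    n_plain <- max(10L, stats::rpois(1, repeat_every))
    plain <- paste(sample(bases, n_plain, replace = TRUE), collapse = "")
    if (stats::runif(1) < 0.5) {
      tract <- strrep(sample(bases, 1), sample(6:12, 1))
    } else {
      unit <- paste(sample(bases, 2, replace = FALSE), collapse = "")
      tract <- strrep(unit, sample(4:8, 1))
    }
    chunks <- c(chunks, plain, tract)
    total <- total + nchar(plain) + nchar(tract)
  }
  seq <- substr(paste(chunks, collapse = ""), 1L, length)
  stats::setNames(seq, chrom)
}

#' Simulation configuration
#'
#' @param genome named character vector of chromosome sequences (e.g. from
#'   [simulate_genome()]).
#' @param n_variants number of truth variants.
#' @param indel_fraction fraction of truth variants that are indels.
#' @param het_fraction fraction of truth variants that are heterozygous.
#' @param strata optional named list of `covote_regions` depth strata.
#' @param seed mandatory RNG seed: the whole simulation is a deterministic
#'   function of the configuration.
#' @return list of class `covote_sim_config`.
#' @export
sim_config <- function(genome, n_variants, indel_fraction = 0.2,
                       het_fraction = 0.6, strata = NULL, seed) {
  if (missing(seed) || is.null(seed)) {
    covote_usage_error("sim_config() requires an explicit seed")
  }
  if (indel_fraction < 0 || indel_fraction > 1 ||
      het_fraction < 0 || het_fraction > 1) {
    covote_usage_error("indel_fraction and het_fraction must lie in [0, 1]")
  }
  glen <- sum(nchar(genome))
  if (glen < 10 * n_variants) {
    covote_usage_error(
      "genome too small: %d bp for %d variants (need >= 10 bp per variant)",
      glen, n_variants)
  }
  structure(list(genome = genome, n_variants = as.integer(n_variants),
                 indel_fraction = indel_fraction, het_fraction = het_fraction,
                 strata = strata, seed = as.integer(seed)),
            class = "covote_sim_config")
}

# Candidate anchor positions: spaced >= 30 bp so normalization (bounded by
# the <= ~16 bp planted tracts) cannot collide two truth keys, with margins
# wide enough for the left-alignment window.
truth_slots <- function(chromseq, margin = 160L, spacing = 30L) {
  L <- nchar(chromseq)
  if (L < 2L * margin + spacing) return(integer(0))
  seq.int(margin, L - margin, by = spacing)
}

#' Generate a truth set
#'
#' Draws `n_variants` distinct variant positions (pairwise >= 30 bp apart),
#' assigns SNV / indel class and het / hom-alt genotype by the configured
#' fractions, and returns the truth call-set in normalized (left-aligned,
#' trimmed) spelling. Deterministic given the configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `reference` (named character) and `truth`
#'   (a normalized `covote_callset` with `caller = "truth"`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "covote_sim_config"))
  withr::local_seed(config$seed)
  genome <- config$genome
  slot_tbl <- bind_rows(lapply(names(genome), function(ch) {
    tibble(chrom = ch, pos = truth_slots(genome[[ch]]))
  }))
  if (nrow(slot_tbl) < config$n_variants) {
    covote_usage_error("genome too small: only %d candidate sites for %d variants",
                       nrow(slot_tbl), config$n_variants)
  }
  picked <- slot_tbl[sort(sample.int(nrow(slot_tbl), config$n_variants)), ]
  n <- nrow(picked)
  is_indel <- stats::runif(n) < config$indel_fraction
  is_het <- stats::runif(n) < config$het_fraction
  bases <- c("A", "C", "G", "T")

  refs <- alts <- character(n)
  for (i in seq_len(n)) {
    ch <- picked$chrom[i]; p <- picked$pos[i]
    anchor <- substr(genome[[ch]], p, p)
    if (!is_indel[i]) {
      refs[i] <- anchor
      alts[i] <- sample(setdiff(bases, anchor), 1)
    } else if (stats::runif(1) < 0.5) {
      len <- sample(1:6, 1) # deletion
      refs[i] <- substr(genome[[ch]], p, p + len)
      alts[i] <- anchor
    } else {
      ins <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
      refs[i] <- anchor # insertion
      alts[i] <- paste0(anchor, ins)
    }
  }
  truth <- tibble(
    chrom = picked$chrom, pos = picked$pos, ref = refs, alt = alts,
    genotype = if_else(is_het, "het", "hom_alt"),
    caller = "truth", line = seq_len(n)
  )
  truth <- normalize_calls(truth, reference = genome)
  dup <- duplicated(truth$key)
  if (any(dup)) {
    warn(sprintf("dropped %d truth variant(s) colliding after normalization",
                 sum(dup)))
    truth <- truth[!dup, ]
  }
  truth <- sort_calls(select(truth, "chrom", "pos", "ref", "alt", "genotype",
                             "vclass", "caller", "key"))
  attr(truth, "normalized") <- "left_aligned"
  class(truth) <- c("covote_callset", class(truth))
  list(reference = genome, truth = truth)
}

#' Per-caller error model
#'
#' @param sensitivity probability the caller emits a call at a truth site.
#' @param fp_rate expected false calls per simulated megabase.
#' @param genotype_error probability an emitted genotype is flipped
#'   (het <-> hom-alt), conditional on detection.
#' @param depth_modifier optional named numeric: stratum label ->
#'   multiplicative sensitivity modifier applied to variants whose anchor
#'   falls in that stratum.
#' @return list of class `covote_caller_model`.
#' @export
caller_model <- function(sensitivity = 0.9, fp_rate = 20,
                         genotype_error = 0.0, depth_modifier = NULL) {
  if (sensitivity < 0 || sensitivity > 1 ||
      genotype_error < 0 || genotype_error > 1 || fp_rate < 0) {
    covote_usage_error("caller_model probabilities must lie in [0, 1], fp_rate >= 0")
  }
  structure(list(sensitivity = sensitivity, fp_rate = fp_rate,
                 genotype_error = genotype_error,
                 depth_modifier = depth_modifier),
            class = "covote_caller_model")
}

flip_genotype <- function(g) {
  if_else(g == "het", "hom_alt", "het")
}

#' Simulate one caller observing a truth set
#'
#' Emits each truth variant independently with probability
#' `sensitivity * depth_modifier[stratum]`, flips its genotype with the
#' model's genotype-error probability, adds Poisson false positives at
#' positions disjoint from the truth set, and re-spells a fraction of
#' emitted indels in an equivalent non-normalized form (right-shifted or
#' un-trimmed) to exercise harmonization. Output is a raw call table, as if
#' freshly read from the caller's VCF.
#'
#' @param truth normalized truth call-set (from [simulate_truth()]).
#' @param reference the genome the truth set was generated on.
#' @param model a [caller_model()].
#' @param caller_id caller label.
#' @param seed RNG seed.
#' @param strata named list of `covote_regions`, required when the model has
#'   a `depth_modifier`.
#' @param respell_prob probability an emitted indel is re-spelled.
#' @return raw call tibble (`chrom`, `pos`, `ref`, `alt`, `gt`, `filter`,
#'   `caller`) suitable for [build_callset()] or [write_calls_vcf()].
#' @export
simulate_caller <- function(truth, reference, model, caller_id, seed,
                            strata = NULL, respell_prob = 0.5) {
  stopifnot(inherits(model, "covote_caller_model"))
  withr::local_seed(seed)
  n <- nrow(truth)
  s_eff <- rep(model$sensitivity, n)
  if (!is.null(model$depth_modifier)) {
    if (is.null(strata)) {
      covote_usage_error("model has a depth_modifier but no strata were supplied")
    }
    for (lab in names(model$depth_modifier)) {
      if (!lab %in% names(strata)) {
        covote_usage_error("depth_modifier stratum '%s' not among strata", lab)
      }
      inside <- in_regions(truth$chrom, truth$pos, strata[[lab]])
      s_eff[inside] <- s_eff[inside] * model$depth_modifier[[lab]]
    }
  }
  detected <- stats::runif(n) < s_eff
  calls <- truth[detected, c("chrom", "pos", "ref", "alt", "genotype", "vclass")]
  flip <- stats::runif(nrow(calls)) < model$genotype_error
  calls$genotype[flip] <- flip_genotype(calls$genotype[flip])

  # re-spell a fraction of indels in an equivalent non-canonical form
  respell <- calls$vclass == "INDEL" & stats::runif(nrow(calls)) < respell_prob
  for (i in which(respell)) {
    sp <- if (stats::runif(1) < 0.5) {
      respell_right(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i],
                    reference)
    } else {
      respell_untrim(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i],
                     reference)
    }
    calls$pos[i] <- sp$pos; calls$ref[i] <- sp$ref; calls$alt[i] <- sp$alt
  }

  # false positives: SNVs at positions disjoint from the truth set
  fp <- vector("list", length(reference))
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(reference)) {
    ch <- names(reference)[k]
    L <- nchar(reference[[ch]])
    n_fp <- stats::rpois(1, model$fp_rate * L / 1e6)
    if (n_fp == 0L) next
    avoid <- truth$pos[truth$chrom == ch]
    cand <- setdiff(truth_slots(reference[[ch]], margin = 30L, spacing = 3L),
                    unlist(lapply(avoid, function(p) (p - 8L):(p + 8L))))
    n_fp <- min(n_fp, length(cand))
    p <- sort(sample(cand, n_fp))
    anchor <- vapply(p, function(x) substr(reference[[ch]], x, x), "")
    fp[[k]] <- tibble(
      chrom = ch, pos = p, ref = anchor,
      alt = vapply(anchor, function(a) sample(setdiff(bases, a), 1), ""),
      genotype = sample(c("het", "hom_alt"), n_fp, replace = TRUE),
      vclass = "SNV")
  }
  out <- bind_rows(calls, bind_rows(fp))
  out <- sort_calls(out)
  tibble(
    chrom = out$chrom, pos = out$pos, ref = out$ref, alt = out$alt,
    gt = gt_string(out$genotype), filter = "PASS", caller = caller_id
  )
}

#' Run a full synthetic study
#'
#' Convenience wrapper: truth set plus one simulated call-set per error
#' model, with per-caller seeds derived from the configuration seed.
#' Optionally writes `ref.fa`, `truth.vcf`, `<caller>.vcf`, `strata/*.bed`
#' and a YAML manifest of the realized parameters to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param models named list of [caller_model()] objects (names are caller
#'   labels).
#' @param out_dir optional output directory.
#' @return list with `reference`, `truth`, `callers` (named list of raw call
#'   tibbles), and `paths` when `out_dir` is given.
#' @export
simulate_study <- function(config, models, out_dir = NULL) {
  stopifnot(inherits(config, "covote_sim_config"), length(models) > 0)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("caller", seq_along(models))
  }
  sim <- simulate_truth(config)
  callers <- imap(models, function(m, label) {
    k <- match(label, names(models))
    simulate_caller(sim$truth, sim$reference, m, caller_id = label,
                    seed = (config$seed + 7919L * k) %% .Machine$integer.max,
                    strata = config$strata)
  })
  out <- list(reference = sim$reference, truth = sim$truth, callers = callers)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(out_dir, "ref.fa"),
      truth = file.path(out_dir, "truth.vcf")
    )
    write_reference_fasta(sim$reference, paths$reference)
    write_calls_vcf(sim$truth, paths$truth, sample_name = "TRUTH")
    paths$callers <- map_chr(names(callers), function(label) {
      p <- file.path(out_dir, paste0(label, ".vcf"))
      write_calls_vcf(callers[[label]], p, sample_name = label)
      p
    })
    if (!is.null(config$strata)) {
      dir.create(file.path(out_dir, "strata"), showWarnings = FALSE)
      paths$strata <- map_chr(names(config$strata), function(lab) {
        p <- file.path(out_dir, "strata",
                       paste0(gsub("[^A-Za-z0-9._-]", "_", lab), ".bed"))
        write_bed_regions(config$strata[[lab]], p)
        p
      })
    }
    manifest <- list(
      seed = config$seed, n_variants = config$n_variants,
      indel_fraction = config$indel_fraction,
      het_fraction = config$het_fraction,
      genome_bp = sum(nchar(sim$reference)),
      n_truth = nrow(sim$truth),
      callers = lapply(models, function(m) {
        list(sensitivity = m$sensitivity, fp_rate = m$fp_rate,
             genotype_error = m$genotype_error,
             depth_modifier = as.list(m$depth_modifier))
      }),
      calls_per_caller = lapply(callers, nrow)
    )
    paths$manifest <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, paths$manifest)
    out$paths <- paths
  }
  out
}
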