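---
title: "Consensus genotyping by two-stage voting: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus genotyping by two-stage voting: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covote)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the voting model and its assumptions, the
harmonization contract the model depends on, the evaluation conventions,
what the synthetic-data generator does and does not emulate, and the
numerical and degenerate-input choices a maintainer should know about.

## The voting model

Let $n$ independent variant callers be run on the same single-sample
alignment, and let each caller's output be reduced (see the next section)
to a set of biallelic calls, each carrying a canonical match key
$(\mathrm{chrom}, \mathrm{pos}, \mathrm{ref}, \mathrm{alt})$ and an
unordered diploid genotype $g \in \{\text{het}, \text{hom-alt}\}$. For
each key in the union of the $n$ call-sets, with detection threshold $m$
and concordance threshold $k$ ($1 \le k \le m \le n$):

* **Stage 1 — detection.** Let $\mathrm{NM}$ be the number of callers
  carrying the key. If $\mathrm{NM} < m$ the site is *low-confidence*.
  With the default simple majority ($n=3$, $m=2$) these are exactly the
  single-tool calls, which are reported as a separate call-set rather than
  discarded: they are enriched for caller-specific artifacts but also
  contain real variants in hard regions, and downstream users can rescue
  them with the NM filter.
* **Stage 2 — genotype concordance.** Otherwise tally the genotypes. If
  the unique most frequent genotype is shared by $\ge k$ callers the site
  is *consensus* with that genotype; if two genotypes tie for the maximum,
  or no genotype reaches $k$, the site is *discordant*.

The three statuses partition the union of input keys; `NM` always equals
the number of detecting callers, for every status.

Assumptions worth stating explicitly:

* **Equal weights.** All callers count the same; there is no
  quality-weighted voting. Caller-reported quality and depth are carried
  through as opaque annotations only.
* **Genotype classes.** Concordance is computed on unordered genotypes
  over {het, hom-alt}; phase is ignored, and a caller asserting 0/0 at a
  site is treated as *not detecting* the variant rather than as a third
  genotype class. Missing genotypes (`./.`) at detected sites are excluded
  from both NM and the tally, with a warning: a call without a genotype
  cannot participate in genotype-level concordance.
* **Ties are conservative.** A stage-2 tie (possible, e.g., at $n=4$,
  $k=2$ with a 2–2 split) is *discordant*, never an arbitrary winner.
  One configuration deserves a note: when two callers detect a site but
  disagree on zygosity while the third is silent ($\mathrm{NM} = 2$,
  maximal tally 1 < $k = 2$), the two-stage scheme forces *discordant*.
  Demoting such sites to low-confidence would also be defensible; we keep
  the two-stage semantics because it follows mechanically from the
  thresholds and keeps the two stages independent.

## Harmonization: why voting needs it

Callers spell the same indel differently — anchored at either end of a
repeat tract, with or without redundant flanking bases, bundled into
multiallelic records. Voting on raw spellings would split the quorum. The
harmonization contract is:

1. **Decomposition.** One biallelic call per alternate allele carried by
   the genotype or listed in ALT, with the genotype remapped onto
   $\{0, 1\}$ for that allele (`1/2` becomes het on both alleles; `1/1`
   het→hom-alt on allele 1 and a dropped 0/0 on allele 2). Dropped
   outputs are kept in an audit attribute, not silently discarded.
2. **Trim + left-align.** Shared suffix bases are trimmed; pure indels are
   shifted left through repeats (extending from the reference window) to
   their leftmost equivalent position; shared prefix bases are trimmed,
   always keeping at least one base per allele. The result is a fixpoint
   of the procedure, and the invariant actually tested is *semantic*:
   applying the raw and the normalized variant to the reference window
   yields the same edited sequence, and every spelling of the same edit
   receives the same match key.

The left-alignment window is $W = 100$ bp (configurable). Repeat tracts
longer than $W$ are pathological in real genomes at indel scale; if the
shift does hit the window edge the variant keeps its current position and
a warning records that the key is not fully canonical, preserving
auditability instead of failing the run. When no reference is supplied at
all, a *trim-only* mode runs prefix/suffix trimming without left-alignment
and the call-set is tagged accordingly — useful for toy data, but keys are
then not comparable across indel placements, and the evaluation module
refuses visibly un-trimmed input.

Two further conventions: chromosome labels are compared after stripping an
optional `chr` prefix (inputs mix dialects; configurable off), and only
records with FILTER `PASS` or `.` enter voting by default. Whether
caller-side filters should be honored before consensus is genuinely
ambiguous — the conservative reading (honor them) is the default and a
flag (`keep_filtered = TRUE`, `--keep-filtered`) admits everything.
Within one caller, duplicate match keys collapse to the first occurrence
with a warning: duplicates indicate upstream artifacts, and
first-occurrence keeps the behaviour deterministic and order-stable.
Symbolic and breakend ALT alleles are skipped with a warning — the
engine's scope is SNVs and small indels, and a structural-variant record
should not abort an otherwise valid call-set.

## Evaluation conventions

A call is correct only when key *and* genotype match the truth set
("genotype-exact"). Three conventions matter:

* **"Specificity" is precision**, $TP/(TP+FP)$. True negatives are not
  well defined genome-wide, and precision is the standard surrogate in
  variant-calling benchmarks; it is monotone in the same direction, so
  comparative statements (consensus vs single caller) carry over. The
  output column is named `specificity` to match the field's reporting
  habit; this paragraph is the definition.
* **A genotype-mismatching call at a truth key is one FP and one FN.**
  The truth variant was not correctly recovered, and the emitted call is
  wrong. (Counting it as FP-only is the main alternative; the FP+FN
  accounting is the strict reading of genotype-exact correctness and is
  what the `FP_genotype` verdict in `confusion_detail()` makes auditable.)
* **Stratum assignment is by normalized anchor position.** An indel
  spanning a stratum boundary belongs to the stratum containing its
  left-aligned anchor base — a single unambiguous rule. Metrics with a
  zero denominator are reported `NA`, not 0 or 1.

Evaluable-region restriction (BED, 0-based half-open; merged on input)
excludes both calls and truth variants outside the regions, so
$TP + FN$ always equals the in-region truth count regardless of the
call-set.

## The synthetic generator

`simulate_genome()` / `simulate_truth()` / `simulate_caller()` emulate the
one structure the engine's claims depend on: $n$ callers observing a
shared truth set *independently*, each with

* `sensitivity` — per-site detection probability, optionally multiplied by
  a per-stratum `depth_modifier` (emulating the loss of sensitivity in
  shallow-coverage regions);
* `genotype_error` — probability a detected variant's genotype is flipped
  het↔hom-alt;
* `fp_rate` — expected false calls per megabase, placed at positions
  disjoint from the truth set (so the confusion matrix of a single caller
  is exactly readable from the model parameters).

Half of emitted indels (configurable) are re-spelled into an equivalent
non-normalized form — right-shifted through the repeat or un-trimmed — so
that harmonization is genuinely exercised rather than bypassed; the
planted homopolymer/dinucleotide repeats in the synthetic genome exist for
the same reason, since left-alignment is only observable in repetitive
context. Truth variants are spaced ≥ 30 bp apart, which exceeds the
maximal left-shift through a planted tract and keeps normalized keys
collision-free by construction.

Under caller independence, consensus detection has the binomial closed
form implemented in `expected_consensus_sensitivity()`:
$P(\text{detected by} \ge m) = \sum_{j \ge m} \binom{n}{j} s^j (1-s)^{n-j}$,
e.g. $3s^2(1-s) + s^3 = 0.972$ for the default majority at $s = 0.9$ —
the quantity the acceptance protocol compares against simulation.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: correlated caller errors (real callers share
alignment and mapping artifacts, so real consensus gains are smaller than
the independence closed form), read-level error and coverage processes
(no FASTQ/BAM), systematic reference bias, multi-nucleotide/complex
variants, and false positives that collide between callers by mechanism
rather than by chance. The simulator validates the *engine*; it does not
certify accuracy numbers on any real genome.

## Numerical and degenerate-input choices

* Voting is deterministic and invariant to call-set and record order;
  outputs are sorted by (chrom, pos, ref, alt) with lexicographic
  chromosome order.
* Simulation is a deterministic function of an integer seed (one
  generator, per-caller seeds derived arithmetically from the study
  seed); identical seeds give byte-identical output files.
* Empty inputs flow through: empty call-sets vote to empty partitions,
  empty region sets have empty membership, empty tables export as
  header-only files.
* A MAF ceiling filter passes variants with *missing* MAF by default:
  absence from the frequency database is evidence of rarity, which is the
  prioritization use case; `keep_missing_maf = FALSE` inverts this.
* The single-sample VCF reader is strict by design — malformed lines are
  errors naming the line number, multi-sample files are rejected — because
  silently mis-parsed input is the worst failure mode for a consensus
  engine. It is cross-checked against an independent VCF parser in the
  test-suite.

## Problem sizes in the test and acceptance protocols

The shipped protocols use sizes chosen to make Monte-Carlo bounds tight at
desk scale: 1000 random voting instances (≤ 4 callers × ≤ 50 sites)
against a brute-force per-site oracle; 500 repeat-context indel families
for the normalization oracle; a 1 Mb genome with 2000 truth variants and
three callers at $s = 0.9$, 20 FP/Mb for the consensus-accuracy analogue
(3 standard errors ≈ 0.011 on the 0.972 closed form); and 4000 truth
variants split over two depth strata (0.95/0.70 generating sensitivities)
for stratified recovery. All complete in a few minutes on one CPU.

## Known limitations

Joint multi-sample genotyping, genotype-likelihood merging, gVCF,
structural/symbolic variants and haplotype-aware truth matching are out of
scope. The consensus is defined purely on detection and genotype
agreement; no caller weighting or quality recalibration is attempted.
"Specificity" being precision means reported values are not comparable to
true-negative-based specificities from targeted panels.
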