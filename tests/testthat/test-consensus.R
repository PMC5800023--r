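# The two-stage voting engine: single-site semantics, call-set level
# behaviour, and the brute-force oracle and invariants over random
# instances.

test_that("vote_site implements the two-stage scheme on canonical cases", {
  p <- voting_params(3, 2, 2)
  unanimous <- vote_site(c(A = "het", B = "het", C = "het"), p)
  expect_equal(unanimous$status, "consensus")
  expect_equal(unanimous$genotype, "het")
  expect_equal(unanimous$nm, 3L)
  expect_equal(unanimous$supporters, "A,B,C")

  majority <- vote_site(c(A = "het", B = "het"), p)
  expect_equal(majority$status, "consensus")
  expect_equal(majority$nm, 2L)

  solo <- vote_site(c(A = "het"), p)
  expect_equal(solo$status, "low_confidence")
  expect_equal(solo$nm, 1L)

  split <- vote_site(c(A = "het", B = "hom_alt"), p)
  expect_equal(split$status, "discordant")
  expect_equal(split$nm, 2L)
  expect_true(is.na(split$genotype))

  # strict all-methods consensus: 3-1 genotype split is discordant, not low
  # confidence — all four tools detected the site
  strict <- vote_site(c(A = "het", B = "het", C = "het", D = "hom_alt"),
                      voting_params(4, 4, 4))
  expect_equal(strict$status, "discordant")
  expect_equal(strict$nm, 4L)

  expect_error(vote_site(character(0), p), "at least one")
  expect_error(vote_site(c(A = "het", B = NA), p), "missing")
  expect_error(voting_params(3, 3, 4), "concordance_min")
})

test_that("call_consensus partitions keys and annotates NM = |detectors|", {
  shared <- lapply(c("A", "B", "C"), function(cl) {
    calls_tbl(seq(10, 50, by = 10), "het") |>
      dplyr::mutate(caller = cl)
  })
  shared[[1]] <- dplyr::bind_rows(shared[[1]],
                                  calls_tbl(99, "het") |>
                                    dplyr::mutate(caller = "A"))
  voted <- call_consensus(shared, voting_params(3, 2, 2))
  expect_equal(sum(voted$status == "consensus"), 5L)
  expect_equal(sum(voted$status == "low_confidence"), 1L)
  expect_equal(sum(voted$status == "discordant"), 0L)
  expect_equal(voted$nm[voted$pos == 99], 1L)
  expect_equal(voted$nm[voted$pos == 10], 3L)
  expect_equal(voted$detectors[voted$pos == 10], "A,B,C")

  # NM equals the detector count even for discordant sites
  disc <- call_consensus(list(
    calls_tbl(10, "het") |> dplyr::mutate(caller = "A"),
    calls_tbl(10, "hom_alt") |> dplyr::mutate(caller = "B"),
    calls_tbl(500, "het") |> dplyr::mutate(caller = "C")),
    voting_params(3, 2, 2))
  expect_equal(disc$nm[disc$status == "discordant"], 2L)
  expect_equal(disc$detectors[disc$status == "discordant"], "A,B")
})

test_that("call_consensus validates inputs and handles empty call-sets", {
  empty <- lapply(c("A", "B", "C"), function(cl) {
    calls_tbl(integer(0), character(0)) |> dplyr::mutate(caller = cl)
  })
  voted <- call_consensus(empty, voting_params(3, 2, 2))
  expect_equal(nrow(voted), 0L)

  dup_labels <- list(calls_tbl(10, "het") |> dplyr::mutate(caller = "A"),
                     calls_tbl(20, "het") |> dplyr::mutate(caller = "A"),
                     calls_tbl(30, "het") |> dplyr::mutate(caller = "B"))
  expect_error(call_consensus(dup_labels, voting_params(3, 2, 2)),
               "duplicate caller labels")
  expect_error(call_consensus(dup_labels[1:2], voting_params(3, 2, 2)),
               "n_callers")
})

test_that("voting is invariant to call-set and record order", {
  withr::local_seed(31)
  inst <- random_instance(3, 40)
  p <- voting_params(3, 2, 2)
  base <- call_consensus(inst, p)
  shuffled <- inst[sample.int(nrow(inst)), ]
  expect_equal(as.data.frame(call_consensus(shuffled, p)),
               as.data.frame(base))
})

test_that("build_consensus matches the brute-force per-site oracle", {
  withr::local_seed(1234)
  combos <- list()
  for (n in 1:4) for (d in 1:n) for (k in 1:d) {
    combos[[length(combos) + 1L]] <- c(n, d, k)
  }
  n_instances <- 0L
  for (rep_i in 1:18) {
    for (cmb in combos) {
      n <- cmb[1]; d <- cmb[2]; k <- cmb[3]
      inst <- random_instance(n, sample(1:50, 1))
      got <- call_consensus(inst, voting_params(n, d, k))
      want <- oracle_consensus(inst, d, k)
      merged <- dplyr::inner_join(tidy(got), want, by = "key",
                                  suffix = c("", ".oracle"))
      expect_equal(nrow(merged), nrow(got))
      expect_identical(merged$status, merged$status.oracle)
      expect_identical(merged$genotype, merged$genotype.oracle)
      expect_identical(merged$nm, as.integer(merged$nm.oracle))
      n_instances <- n_instances + 1L
    }
  }
  expect_gte(n_instances, 360L)
})

test_that("partition, subset and monotonicity invariants hold", {
  withr::local_seed(77)
  for (rep_i in 1:25) {
    n <- sample(2:4, 1)
    inst <- random_instance(n, sample(5:50, 1))
    input_keys <- sort(unique(inst$key))

    sizes <- matrix(NA_integer_, n, n)
    for (d in 1:n) for (k in 1:d) {
      voted <- call_consensus(inst, voting_params(n, d, k))
      # partition of the input key union, no invented variants
      expect_identical(sort(voted$key), input_keys)
      expect_identical(anyDuplicated(voted$key), 0L)
      # supporters are always a subset of detectors
      for (i in seq_len(nrow(voted))) {
        sup <- strsplit(voted$supporters[i], ",")[[1]]
        det <- strsplit(voted$detectors[i], ",")[[1]]
        expect_true(all(sup %in% det))
        expect_equal(voted$nm[i], length(det))
      }
      sizes[d, k] <- sum(voted$status == "consensus")
    }
    # raising either threshold never enlarges the consensus set
    for (d in 1:n) for (k in 1:d) {
      if (d > 1 && k <= d - 1) expect_lte(sizes[d, k], sizes[d - 1, k])
      if (k > 1) expect_lte(sizes[d, k], sizes[d, k - 1])
    }
  }
})

test_that("with both thresholds at 1, consensus is the full union", {
  withr::local_seed(55)
  for (n in 2:4) {
    inst <- random_instance(n, 30)
    voted <- call_consensus(inst, voting_params(n, 1, 1))
    expect_equal(sum(voted$status == "low_confidence"), 0L)
    # a site is discordant only on an exact genotype tie; otherwise it is
    # consensus with the (unique) majority genotype
    ties <- tidy(voted)[voted$status == "discordant", ]
    for (key_i in ties$key) {
      g <- inst$genotype[inst$key == key_i]
      expect_equal(sum(g == "het"), sum(g == "hom_alt"))
    }
  }
})

test_that("glance and tidy summarise the voted call-set faithfully", {
  withr::local_seed(10)
  inst <- random_instance(3, 25)
  voted <- call_consensus(inst, voting_params(3, 2, 2))
  g <- glance(voted)
  expect_equal(g$n_sites, nrow(voted))
  expect_equal(g$n_consensus + g$n_low_confidence + g$n_discordant,
               g$n_sites)
  expect_s3_class(tidy(voted), "tbl_df")
  expect_false(inherits(tidy(voted), "covote_consensus"))
  expect_s3_class(autoplot(voted), "ggplot")
})
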