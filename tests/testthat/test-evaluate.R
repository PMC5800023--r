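# Genotype-exact benchmarking: hand-computed confusion matrices, region
# restriction, stratification, and the self-evaluation identity.

test_that("confusion counts match the hand-worked mixed case", {
  truth <- calls_tbl(c(10, 20), c("het", "hom_alt"))
  calls <- calls_tbl(c(10, 20, 30), c("het", "het", "het"))
  ev <- evaluate_calls(calls, truth)
  all_row <- tidy(ev)[tidy(ev)$vclass == "ALL", ]
  # k1 exact match -> TP; k2 genotype mismatch -> FP and FN; k3 novel -> FP
  expect_equal(all_row$tp, 1L)
  expect_equal(all_row$fp, 2L)
  expect_equal(all_row$fn, 1L)
  expect_equal(all_row$sensitivity, 0.5)
  expect_equal(all_row$specificity, 1 / 3)

  detail <- confusion_detail(ev)
  expect_equal(sort(detail$verdict[detail$role == "call"]),
               c("FP_genotype", "FP_novel", "TP"))
  expect_equal(sum(detail$verdict == "FN"), 1L)
})

test_that("evaluating a call-set against itself is perfect", {
  withr::local_seed(5)
  truth <- calls_tbl(sample(seq(10, 5000, by = 10), 80),
                     sample(c("het", "hom_alt"), 80, replace = TRUE))
  ev <- evaluate_calls(truth, truth)
  expect_true(all(tidy(ev)$sensitivity == 1, na.rm = TRUE))
  expect_true(all(tidy(ev)$specificity == 1, na.rm = TRUE))
  expect_equal(sum(tidy(ev)$fp), 0L)
})

test_that("region restriction excludes calls and truth outside regions", {
  truth <- calls_tbl(c(10, 20), c("het", "hom_alt"))
  calls <- calls_tbl(c(10, 20, 30), c("het", "het", "het"))
  # regions covering positions 1..25 only: the novel call at 30 vanishes
  rg <- region_set("1", 0, 25, label = "covered")
  ev <- evaluate_calls(calls, truth, regions = rg)
  all_row <- tidy(ev)[tidy(ev)$vclass == "ALL", ]
  expect_equal(all_row$tp, 1L)
  expect_equal(all_row$fp, 1L)
  expect_equal(all_row$fn, 1L)
  expect_equal(all_row$stratum, "covered")
})

test_that("ten micro-fixtures reproduce hand-computed TP/FP/FN", {
  rg_all <- NULL
  # each case: truth genotypes, call genotypes (by position), regions,
  # expected c(tp, fp, fn) for the ALL class
  cases <- list(
    list(t = c(`10` = "het"), c = c(`10` = "het"), r = rg_all, e = c(1, 0, 0)),
    list(t = c(`10` = "het"), c = c(`10` = "hom_alt"), r = rg_all, e = c(0, 1, 1)),
    list(t = c(`10` = "hom_alt"), c = c(`20` = "hom_alt"), r = rg_all, e = c(0, 1, 1)),
    list(t = c(`10` = "het", `20` = "het"), c = c(`10` = "het"), r = rg_all, e = c(1, 0, 1)),
    list(t = character(0), c = c(`10` = "het"), r = rg_all, e = c(0, 1, 0)),
    list(t = c(`10` = "het"), c = character(0), r = rg_all, e = c(0, 0, 1)),
    list(t = character(0), c = character(0), r = rg_all, e = c(0, 0, 0)),
    list(t = c(`10` = "het", `50` = "het"), c = c(`10` = "het", `50` = "het"),
         r = region_set("1", 0, 30), e = c(1, 0, 0)),
    list(t = c(`50` = "hom_alt"), c = c(`10` = "het"),
         r = region_set("1", 0, 30), e = c(0, 1, 0)),
    list(t = c(`10` = "het", `20` = "hom_alt", `30` = "het"),
         c = c(`10` = "het", `20` = "het", `40` = "hom_alt"),
         r = rg_all, e = c(1, 2, 2))
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    truth <- calls_tbl(as.integer(names(cs$t)), unname(cs$t))
    calls <- calls_tbl(as.integer(names(cs$c)), unname(cs$c))
    ev <- tidy(evaluate_calls(calls, truth, regions = cs$r))
    got <- unlist(ev[ev$vclass == "ALL", c("tp", "fp", "fn")])
    expect_equal(unname(got), cs$e, info = paste("case", i))
  }
})

test_that("metrics are NA when a denominator is zero", {
  ev <- tidy(evaluate_calls(calls_tbl(integer(0), character(0)),
                            calls_tbl(integer(0), character(0))))
  expect_true(all(is.na(ev$sensitivity)))
  expect_true(all(is.na(ev$specificity)))
})

test_that("evaluation rejects un-normalized input", {
  bad <- tibble::tibble(chrom = "1", pos = 10L, ref = "CAT", alt = "CGT",
                        genotype = "het", key = "1:10:CAT:CGT")
  expect_error(evaluate_calls(bad, calls_tbl(10, "het")), "un-normalized")
  expect_error(evaluate_calls(tibble::tibble(chrom = "1", pos = 1L),
                              calls_tbl(10, "het")), "not normalized")
})

test_that("tp + fn is conserved at the truth-set size regardless of calls", {
  withr::local_seed(8)
  truth <- calls_tbl(seq(10, 800, by = 10),
                     sample(c("het", "hom_alt"), 80, replace = TRUE))
  for (rep_i in 1:5) {
    m <- sample(0:60, 1)
    calls <- calls_tbl(sample(seq(10, 1600, by = 10), m),
                       sample(c("het", "hom_alt"), m, replace = TRUE))
    ev <- tidy(evaluate_calls(calls, truth))
    all_row <- ev[ev$vclass == "ALL", ]
    expect_equal(all_row$tp + all_row$fn, nrow(truth))
    snv_row <- ev[ev$vclass == "SNV", ]
    expect_equal(snv_row$tp + snv_row$fn, nrow(truth))
  }
})

test_that("stratified evaluation is additive over a partition", {
  withr::local_seed(12)
  truth <- calls_tbl(sample(10:4000, 150),
                     sample(c("het", "hom_alt"), 150, replace = TRUE))
  calls <- calls_tbl(sample(10:4000, 120),
                     sample(c("het", "hom_alt"), 120, replace = TRUE))
  strata <- list(left = region_set("1", 0, 2000, "left"),
                 right = region_set("1", 2000, 4000, "right"))
  res <- stratify_evaluation(calls, truth, strata)
  whole <- tidy(evaluate_calls(calls, truth,
                               regions = region_set("1", 0, 4000)))
  res_all <- tidy(res)[tidy(res)$vclass == "ALL", ]
  whole_all <- whole[whole$vclass == "ALL", ]
  expect_equal(sum(res_all$tp), whole_all$tp)
  expect_equal(sum(res_all$fp), whole_all$fp)
  expect_equal(sum(res_all$fn), whole_all$fn)

  # an empty stratum yields zero counts and NA metrics
  res2 <- tidy(evaluate_calls(calls, truth,
                              regions = region_set("1", 5000, 6000, "empty")))
  expect_true(all(res2$tp + res2$fp + res2$fn == 0))
  expect_true(all(is.na(res2$sensitivity)))

  expect_error(stratify_evaluation(calls, truth, list()), "non-empty")
})

test_that("eval objects tidy, glance and plot", {
  truth <- calls_tbl(c(10, 20), c("het", "hom_alt"))
  ev <- evaluate_calls(truth, truth)
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_equal(g$sensitivity, 1)
  expect_s3_class(autoplot(ev), "ggplot")
})
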