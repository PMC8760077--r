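# Filtering cascade, pseudocounted enrichment ratio, prioritisation and
# bait-versus-bait comparison.

test_that("single-peptide filter respects its boundary and is idempotent", {
  tab <- make_table(make_records(c("P1", "P2", "P3"),
                                 unique_peptides = c(1L, 2L, 1L)))
  removed <- drop_single_peptide(tab, mode = "remove")
  expect_identical(removed$records$accession, "P2")
  expect_identical(drop_single_peptide(removed, mode = "remove"), removed)

  flagged <- drop_single_peptide(drop_single_peptide(tab))
  expect_identical(flagged$records$filter_flags,
                   c("single_peptide", "", "single_peptide"))

  empty <- make_table(make_records(character(0)))
  expect_identical(nrow(drop_single_peptide(empty)$records), 0L)
})

test_that("background subtraction removes proteins with >2 control unique peptides", {
  tab <- make_table(make_records(c("P1", "P2", "P3", "P4")))
  ctrl <- make_table(make_records(c("P1", "P2", "P9"),
                                  unique_peptides = c(3L, 2L, 6L)),
                     condition = "control", bait = "parental")
  out <- subtract_background(tab, ctrl, mode = "remove")
  # P1: 3 > 2 removed; P2: exactly 2 kept; P3/P4 absent from control kept
  expect_identical(out$records$accession, c("P2", "P3", "P4"))
  relaxed <- subtract_background(tab, ctrl, max_control_unique = 3L,
                                 mode = "remove")
  expect_identical(relaxed$records$accession, c("P1", "P2", "P3", "P4"))

  empty_ctrl <- make_table(make_records(character(0)), condition = "control")
  expect_warning(unchanged <- subtract_background(tab, empty_ctrl), "empty")
  expect_identical(unchanged, tab)
})

test_that("the two filters commute and flagged rows never reach prioritisation", {
  for (seed in 1:5) {
    set.seed(seed)
    tab <- make_table(random_records(40))
    ctrl <- make_table(random_records(25), condition = "control",
                       bait = "parental")
    ab <- subtract_background(drop_single_peptide(tab), ctrl)
    ba <- drop_single_peptide(subtract_background(tab, ctrl))
    surv_ab <- ab$records$accession[!nzchar(ab$records$filter_flags)]
    surv_ba <- ba$records$accession[!nzchar(ba$records$filter_flags)]
    expect_identical(sort(surv_ab), sort(surv_ba))

    enr <- build_enrichment(ab, drop_single_peptide(make_table(
      random_records(40), condition = "reference")))
    pri <- prioritize(enr, min_ratio = 0, min_score = 0)
    flagged <- ab$records$accession[nzchar(ab$records$filter_flags)]
    expect_length(intersect(pri$accession, flagged), 0)
  }
})

test_that("cascade equals the brute-force row-predicate oracle", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    trap <- random_records(sample(5:50, 1))
    ctrl <- random_records(sample(3:30, 1))
    got <- subtract_background(
      drop_single_peptide(make_table(trap), mode = "remove"),
      make_table(ctrl, condition = "control", bait = "parental"),
      mode = "remove")
    expect_identical(sort(got$records$accession),
                     oracle_survivors(trap, ctrl))
  }
})

test_that("replicate aggregation pools counts and keeps the best score", {
  t1 <- make_table(make_records(c("P1", "P2"), psms = c(4L, 2L),
                                unique_peptides = c(2L, 1L),
                                ms_score = c(100, 50)), sample_id = "r1")
  t2 <- make_table(make_records(c("P1", "P3"), psms = c(6L, 8L),
                                unique_peptides = c(3L, 4L),
                                ms_score = c(220, 90)),
                   sample_id = "r2", replicate = 2L)
  t3 <- make_table(make_records("P1", psms = 5L, ms_score = 10),
                   sample_id = "r3", replicate = 3L)
  agg <- aggregate_replicates(list(t1, t2, t3))
  expect_identical(agg$records$psms[agg$records$accession == "P1"], 15L)
  expect_equal(agg$records$ms_score[agg$records$accession == "P1"], 220)
  # union with missing-as-zero
  expect_setequal(agg$records$accession, c("P1", "P2", "P3"))
  expect_identical(agg$records$psms[agg$records$accession == "P3"], 8L)

  m <- aggregate_replicates(list(t1, t2, t3), method = "mean_rounded")
  expect_identical(m$records$psms[m$records$accession == "P1"], 5L)

  expect_identical(aggregate_replicates(list(t1)), t1)
  bad <- make_table(make_records("P1"), condition = "reference")
  expect_error(aggregate_replicates(list(t1, bad)), "bait",
               class = "trapint_validation_error")
})

test_that("enrichment ratio implements the pseudocount rule", {
  expect_equal(enrichment_ratio(10L, 4L), 2.5)
  expect_equal(enrichment_ratio(4L, NA), 4.0)
  expect_equal(enrichment_ratio(0L, 7L), 0.0)
  expect_equal(enrichment_ratio(3L, 0L), 3.0)   # zero denominator -> +1 rule
  expect_error(enrichment_ratio(NA, NA), "absent",
               class = "trapint_validation_error")
  expect_error(enrichment_ratio(-1L, 2L), class = "trapint_validation_error")
})

test_that("enrichment ratio is strictly increasing in trap PSMs and always finite", {
  for (ref in list(0L, 1L, 7L, NA)) {
    r <- enrichment_ratio(0:60, rep(ref, 61))
    expect_true(all(diff(r) > 0))
    expect_true(all(is.finite(r)))
    expect_true(all(r[-1] > 0))
  }
})

test_that("build_enrichment scores trap proteins and segregates reference-only ones", {
  trap <- make_table(make_records(c("P1", "P2"), psms = c(10L, 5L),
                                  ms_score = c(500, 80)))
  ref <- make_table(make_records(c("P1", "P9"), psms = c(4L, 3L)),
                    condition = "reference")
  enr <- build_enrichment(trap, ref)
  expect_equal(enr$ratio, c(2.5, 5.0))
  expect_equal(enr$ms_score, c(500, 80))   # score comes from the trap sample
  expect_identical(attr(enr, "reference_only")$accession, "P9")

  empty <- build_enrichment(make_table(make_records(character(0))), ref)
  expect_identical(nrow(empty), 0L)
})

test_that("prioritisation filters on both criteria and ranks deterministically", {
  enr <- build_enrichment(
    make_table(make_records(c("B", "A", "C", "D"), psms = c(9L, 9L, 4L, 30L),
                            ms_score = c(50, 50, 500, 40))),
    make_table(make_records(c("B", "A", "C", "D"), psms = c(3L, 3L, 1L, 29L)),
               condition = "reference"))
  out <- prioritize(enr, min_ratio = 2, min_score = 0,
                    strategy = "ratio_first")
  # D fails min_ratio (30/29); A/B tie on (ratio 3, score 50) -> accession order
  expect_identical(out$accession, c("C", "A", "B"))
  expect_identical(out$rank, 1:3)
  by_score <- prioritize(enr, min_ratio = 2, strategy = "score_first")
  expect_identical(by_score$accession, c("C", "A", "B"))
  high_score <- prioritize(enr, min_ratio = 0, min_score = 45)
  expect_setequal(high_score$accession, c("A", "B", "C"))
})

test_that("bait comparison outer-joins with presence flags", {
  wt <- build_enrichment(
    make_table(make_records(c("SUMO1", "SUMO2"), psms = c(10L, 4L))),
    make_table(make_records("SUMO1", psms = 2L), condition = "reference"))
  mut <- build_enrichment(
    make_table(make_records("SUMO1", psms = 3L), bait = "mutant"),
    make_table(make_records("SUMO1", psms = 3L), bait = "mutant",
               condition = "reference"))
  rows <- compare_baits(wt, mut)
  s1 <- rows[rows$accession == "SUMO1", ]
  expect_equal(s1$ratio_wt, 5)
  expect_equal(s1$ratio_mut, 1)
  expect_true(s1$present_wt && s1$present_mut)
  s2 <- rows[rows$accession == "SUMO2", ]
  expect_equal(s2$ratio_wt, 4)
  expect_true(is.na(s2$ratio_mut) && !s2$present_mut)

  disjoint <- compare_baits(wt[wt$accession == "SUMO2", ], mut)
  expect_true(all(xor(disjoint$present_wt, disjoint$present_mut)))
})
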