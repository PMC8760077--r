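# Network construction at the confidence cutoff, and Fisher's-exact
# over-representation checked against exhaustive enumeration.

edges_df <- function(a, b, s) data.frame(symbol_a = a, symbol_b = b, score = s)

test_that("network keeps confident edges between hits and drops singletons", {
  edges <- edges_df(c("A", "B", "A", "X"), c("B", "C", "D", "Y"),
                    c(0.8, 0.6, 0.9, 0.99))
  g <- build_network(c("A", "B", "C", "D"), edges, cutoff = 0.7)
  # B-C falls below cutoff, X-Y is not between hits; C never connects
  expect_setequal(igraph::V(g)$name, c("A", "B", "D"))
  expect_equal(igraph::ecount(g), 2)

  empty <- build_network(c("A", "B"), edges_df("A", "B", 0.5))
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(igraph::vcount(build_network(character(0), edges)), 0)
  expect_error(build_network("A", edges, cutoff = 2),
               class = "trapint_validation_error")
})

test_that("network output is invariant to input row order", {
  set.seed(7)
  syms <- LETTERS[1:12]
  pairs <- t(utils::combn(syms, 2))
  edges <- edges_df(pairs[, 1], pairs[, 2], round(runif(nrow(pairs)), 3))
  hits <- sample(syms, 8)
  g1 <- build_network(hits, edges)
  g2 <- build_network(hits, edges[sample(nrow(edges)), ])
  expect_identical(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
})

test_that("Fisher p-values match frozen exhaustive-enumeration values", {
  # universe 20, hits 5, set of 5, full overlap: 1 of choose(20,5) hit sets
  u20 <- sprintf("U%02d", 1:20)
  res <- fisher_enrichment(u20[1:5], list(S = u20[1:5]), universe = u20)
  expect_equal(res$p_value, 1 / choose(20, 5))
  expect_equal(res$neg_log10_p, -log10(res$p_value))

  # universe 10, hits 3, set of 4, overlap 2:
  # (C(4,2)*C(6,1) + C(4,3)*C(6,0)) / C(10,3) = 40/120
  u10 <- sprintf("U%02d", 1:10)
  res2 <- fisher_enrichment(u10[1:3], list(S = u10[c(1, 2, 5, 6)]),
                            universe = u10)
  expect_equal(res2$p_value, 1 / 3)
  expect_identical(res2$overlap, 2L)

  # zero overlap is never significant one-sided
  res3 <- fisher_enrichment(u10[1:3], list(S = u10[8:10]), universe = u10)
  expect_equal(res3$p_value, 1)
})

test_that("Fisher p equals enumeration and fisher.test on random small cases", {
  for (seed in 1:8) {
    set.seed(seed)
    N <- sample(8:16, 1)
    universe <- sprintf("G%02d", seq_len(N))
    hits <- sample(universe, sample(2:5, 1))
    set_members <- sample(universe, sample(2:7, 1))
    res <- fisher_enrichment(hits, list(S = set_members), universe = universe)
    expect_equal(res$p_value,
                 oracle_fisher_p(universe, hits, set_members),
                 tolerance = 1e-12)
    q <- res$overlap; m <- res$set_size; k <- res$hit_count
    tab <- matrix(c(q, k - q, m - q, N - m - k + q), 2)
    expect_equal(res$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("p is invariant under symbol relabeling and monotone in overlap", {
  u <- sprintf("G%02d", 1:18)
  hits <- u[1:6]
  res_a <- fisher_enrichment(hits, list(S = u[c(1:3, 10:12)]), universe = u)
  relabel <- stats::setNames(sprintf("H%02d", 1:18), u)
  res_b <- fisher_enrichment(relabel[hits],
                             list(S = unname(relabel[c(1:3, 10:12)])),
                             universe = unname(relabel))
  expect_equal(res_a$p_value, res_b$p_value)

  # fixed margins (set size 6, hits 6), growing overlap
  ps <- vapply(0:6, function(q) {
    set_m <- c(u[seq_len(q)], u[seq_len(6 - q) + 10])
    fisher_enrichment(hits, list(S = set_m), universe = u)$p_value
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("hits outside the universe are an error naming the symbol", {
  expect_error(
    fisher_enrichment(c("IN", "ROGUE"), list(S = c("IN", "OTHER")),
                      universe = c("IN", "OTHER")),
    "ROGUE", class = "trapint_validation_error")
})

test_that("term filtering is inclusive at the -log10 threshold", {
  res <- data.frame(set_name = c("a", "b", "c"),
                    p_value = c(0.05, 0.02, 0.002),
                    neg_log10_p = -log10(c(0.05, 0.02, 0.002)))
  expect_identical(filter_terms(res, 1.3)$set_name, c("a", "b", "c"))
  expect_identical(filter_terms(res, 2.0)$set_name, "c")
  expect_identical(nrow(filter_terms(res[0, ], 1.3)), 0L)
})

test_that("optional BH adjustment is available but off by default", {
  u <- sprintf("G%02d", 1:20)
  sets <- list(S1 = u[1:5], S2 = u[6:10], S3 = u[11:15])
  res <- fisher_enrichment(u[1:5], sets, universe = u)
  expect_null(res$p_adjust)
  res_bh <- fisher_enrichment(u[1:5], sets, universe = u, adjust = "BH")
  expect_equal(res_bh$p_adjust, stats::p.adjust(res_bh$p_value, "BH"))
  expect_error(filter_terms(res, 1.3, use_adjusted = TRUE), "p_adjust")
})
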