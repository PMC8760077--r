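# Hit-network construction at a confidence cutoff and Fisher's-exact
# gene-set over-representation (in-package replacement for the STRING /
# Enrichr web steps: their exported data are consumed as inputs, their
# computation happens here).

#' Build the hit interaction network
#'
#' Induces the subgraph of the weighted interaction edge list on the hit
#' symbols, keeps edges with combined score at or above `cutoff` (the usual
#' high-confidence threshold is 0.7), and removes unconnected singleton
#' nodes. Node and edge order are deterministic (lexicographic), independent
#' of input row order.
#'
#' @param hits character vector of hit gene symbols (case-insensitive).
#' @param edges data.frame with columns `symbol_a`, `symbol_b`, `score` on
#'   \[0, 1\], as returned by [read_edge_scores()].
#' @param cutoff minimum combined score for an edge, in \[0, 1\]; default 0.7.
#' @return An [igraph][igraph::graph_from_data_frame] graph with edge
#'   attribute `score`; empty when no edge survives.
#' @export
build_network <- function(hits, edges, cutoff = 0.7) {
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1)
    validation_error("cutoff must lie in [0, 1]")
  hits <- unique(clean_symbols(hits))
  hits <- hits[nzchar(hits)]
  edges <- normalize_edge_scores(edges[c("symbol_a", "symbol_b", "score")])
  keep <- edges$symbol_a %in% hits & edges$symbol_b %in% hits &
    edges$score >= cutoff
  el <- edges[keep, , drop = FALSE]
  el <- el[order(el$symbol_a, el$symbol_b), , drop = FALSE]
  # built from surviving edges only, so degree-0 nodes never enter
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = sort(unique(c(el$symbol_a,
                                                         el$symbol_b))))
}

network_edge_table <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!nrow(el))
    return(data.frame(symbol_a = character(0), symbol_b = character(0),
                      score = numeric(0)))
  out <- data.frame(symbol_a = pmin(el$from, el$to),
                    symbol_b = pmax(el$from, el$to),
                    score = el$score, stringsAsFactors = FALSE)
  out[order(out$symbol_a, out$symbol_b), , drop = FALSE]
}

network_summary <- function(graph) {
  comp <- igraph::components(graph)
  list(n_nodes = igraph::vcount(graph),
       n_edges = igraph::ecount(graph),
       n_components = comp$no,
       nodes = sort(igraph::V(graph)$name))
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each gene set, tests whether the hit list overlaps the set more than
#' expected by chance, using the one-sided (over-representation) Fisher's
#' exact test on the 2x2 table (overlap, hits - overlap, set - overlap,
#' rest). The p-value is the upper hypergeometric tail
#' `P(X >= overlap)` with `X ~ Hypergeom(set_size, universe - set_size,
#' hit_count)`. Sets are intersected with the universe before testing.
#'
#' @param hits character vector of hit symbols; must all lie in `universe`.
#' @param gene_sets named list of character vectors (see [read_gene_sets()]).
#' @param universe background symbol universe; defaults to the union of all
#'   gene-set members (the collection-defined background convention).
#' @param adjust `"none"` (default; raw p-values, matching threshold
#'   filtering on -log10 P) or `"BH"` to add Benjamini-Hochberg adjusted
#'   p-values in a `p_adjust` column.
#' @return data.frame of class `gene_set_results` with columns `set_name`,
#'   `set_size`, `overlap`, `universe_size`, `hit_count`, `p_value`,
#'   `neg_log10_p`, sorted by p-value then set name.
#' @export
fisher_enrichment <- function(hits, gene_sets, universe = NULL,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(gene_sets))
  hits <- unique(clean_symbols(hits))
  hits <- hits[nzchar(hits)]
  if (is.null(universe)) {
    universe <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  } else {
    universe <- unique(clean_symbols(universe))
    universe <- universe[nzchar(universe)]
  }
  stray <- setdiff(hits, universe)
  if (length(stray))
    validation_error(sprintf("hit symbol(s) not in universe: %s",
                             paste(stray, collapse = ", ")))
  N <- length(universe)
  k <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(clean_symbols(gene_sets[[nm]]), universe)
    m <- length(members)
    q <- length(intersect(hits, members))
    # upper tail P(X >= q), exact hypergeometric
    p <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, overlap = q,
               universe_size = N, hit_count = k,
               p_value = p, neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(set_name = character(0), set_size = integer(0),
               overlap = integer(0), universe_size = integer(0),
               hit_count = integer(0), p_value = numeric(0),
               neg_log10_p = numeric(0))
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_set_results", "data.frame")
  out
}

#' Filter over-representation results on -log10 p
#'
#' Keeps results whose `-log10(p)` is at or above the threshold. The
#' comparison is inclusive, so the conventional thresholds 1.3 and 2 keep
#' p = 0.05 and p = 0.01 exactly. No multiple-testing adjustment is applied
#' unless the results carry a `p_adjust` column and `use_adjusted = TRUE`.
#'
#' @param results a `gene_set_results` data.frame.
#' @param neg_log10_threshold nonnegative threshold on -log10(p); 1.3
#'   corresponds to p = 0.05, 2 to p = 0.01.
#' @param use_adjusted filter on `-log10(p_adjust)` instead of the raw p.
#' @return The filtered results, order preserved.
#' @export
filter_terms <- function(results, neg_log10_threshold,
                         use_adjusted = FALSE) {
  stopifnot(is.data.frame(results), neg_log10_threshold >= 0)
  p <- if (use_adjusted) {
    if (is.null(results$p_adjust))
      validation_error("results carry no p_adjust column; run fisher_enrichment(adjust = 'BH')")
    results$p_adjust
  } else {
    results$p_value
  }
  out <- results[-log10(p) >= neg_log10_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
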