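# Shared fixtures and independent oracles. Each oracle re-derives its
# quantity by brute force (enumeration or grid search) so it never shares a
# code path with the implementation it checks.

make_records <- function(accession, unique_peptides = 2L, psms = 5L,
                         ms_score = 100, gene_symbol = NULL) {
  n <- length(accession)
  if (is.null(gene_symbol))
    gene_symbol <- if (n) paste0("G", toupper(accession)) else character(0)
  data.frame(accession = accession,
             gene_symbol = gene_symbol,
             unique_peptides = rep_len(unique_peptides, n),
             psms = rep_len(psms, n),
             ms_score = rep_len(ms_score, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_table <- function(records, condition = "trap", bait = "wt",
                       sample_id = "s1", replicate = 1L) {
  identification_table(records, sample_id = sample_id, bait = bait,
                       condition = condition, replicate = replicate)
}

# Random but reproducible identification records honouring the invariants.
random_records <- function(n, prefix = "P") {
  psms <- sample(1:25, n, replace = TRUE)
  make_records(sprintf("%s%03d", prefix, seq_len(n)),
               unique_peptides = pmax(1L, pmin(psms, sample(1:6, n, TRUE))),
               psms = psms,
               ms_score = round(stats::runif(n, 10, 2000), 1))
}

# Brute-force filtering-cascade oracle: re-evaluates the two row predicates
# independently, one row at a time.
oracle_survivors <- function(trap_records, control_records,
                             max_control_unique = 2L) {
  keep <- vapply(seq_len(nrow(trap_records)), function(i) {
    r <- trap_records[i, ]
    if (r$unique_peptides <= 1L) return(FALSE)
    j <- match(r$accession, control_records$accession)
    if (!is.na(j) &&
        control_records$unique_peptides[[j]] > max_control_unique)
      return(FALSE)
    TRUE
  }, logical(1))
  sort(trap_records$accession[keep])
}

# Exhaustive hypergeometric-tail oracle: enumerates every possible hit set
# of the given size and counts how many reach the observed overlap.
oracle_fisher_p <- function(universe, hits, set_members) {
  set_members <- intersect(set_members, universe)
  q <- length(intersect(hits, set_members))
  combos <- utils::combn(universe, length(hits))
  hit_counts <- apply(combos, 2, function(h)
    length(intersect(h, set_members)))
  mean(hit_counts >= q)
}

# Nested-grid least-squares oracle for the one-site recovery model.
oracle_fit_one_site <- function(times, ys, iters = 9) {
  th_range <- c(1e-3, 100)
  ym_range <- c(1e-3, 1.5)
  best <- c(ymax = NA, t_half = NA, ssr = Inf)
  for (it in seq_len(iters)) {
    ths <- seq(th_range[1], th_range[2], length.out = 30)
    yms <- seq(ym_range[1], ym_range[2], length.out = 30)
    for (th in ths) {
      x <- times / (th + times)
      for (ym in yms) {
        ssr <- sum((ys - ym * x)^2)
        if (ssr < best[["ssr"]]) best <- c(ymax = ym, t_half = th, ssr = ssr)
      }
    }
    th_span <- diff(th_range) / 10
    ym_span <- diff(ym_range) / 10
    th_range <- c(max(1e-4, best[["t_half"]] - th_span),
                  best[["t_half"]] + th_span)
    ym_range <- c(max(1e-4, best[["ymax"]] - ym_span),
                  min(1.5, best[["ymax"]] + ym_span))
  }
  as.list(best)
}

# Applies the documented cascade to one trap/ref/control trio of files laid
# out like the study's processed interactome tables, returning the survivor
# count and the enrichment records; used by the (data-dependent) published-
# counts acceptance check.
reproduce_published_counts <- function(trap_path, ref_path, control_path,
                                       max_control_unique = 2L) {
  trap <- read_identifications(trap_path, condition = "trap")
  ref <- read_identifications(ref_path, condition = "reference")
  ctrl <- read_identifications(control_path, condition = "control")
  trap <- subtract_background(drop_single_peptide(trap, "remove"), ctrl,
                              max_control_unique, mode = "remove")
  ref <- subtract_background(drop_single_peptide(ref, "remove"), ctrl,
                             max_control_unique, mode = "remove")
  enr <- build_enrichment(trap, ref)
  list(count = nrow(enr), records = enr)
}
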