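# End-to-end orchestration: a structured config drives
# ingest -> aggregate -> filter -> enrich -> prioritize -> compare ->
# network -> over-representation, with a run manifest recording row counts
# per stage. The command-line entry point lives in inst/exec/trapint.
#
# Config files are JSON (the one structured-text format guaranteed in the
# dependency footprint); CLI flags override config values.

#' Assemble a pipeline configuration
#'
#' @param sample_sheet path to a TSV with columns `path`, `sample_id`,
#'   `bait`, `condition` (`trap` / `reference` / `control`), `replicate`.
#'   Control samples are matched to baits by the `control_bait` field.
#' @param edges_path optional path to a weighted edge list for the network
#'   stage.
#' @param gene_sets_path optional GMT path for the over-representation stage.
#' @param out_dir output directory (created if needed).
#' @param control_bait bait label of the negative-control sample(s) in the
#'   sheet; default `"parental"`.
#' @param max_control_unique,min_ratio,min_score,strategy filter and
#'   prioritisation settings (see [subtract_background()], [prioritize()]).
#' @param aggregate `"sum"` or `"mean_rounded"` replicate pooling.
#' @param network_cutoff minimum interaction score for network edges (0.7).
#' @param neg_log10_threshold -log10(p) cutoff for term filtering (1.3
#'   keeps p <= 0.05; use 2 for p <= 0.01).
#' @param seed integer seed echoed into the manifest.
#' @param quiet suppress stage logging to stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, edges_path = NULL,
                            gene_sets_path = NULL, out_dir = "trapint_out",
                            control_bait = "parental",
                            max_control_unique = 2L, min_ratio = 2,
                            min_score = 0,
                            strategy = c("ratio_first", "score_first"),
                            aggregate = c("sum", "mean_rounded"),
                            network_cutoff = 0.7,
                            neg_log10_threshold = 1.3,
                            seed = 1L, quiet = FALSE) {
  cfg <- list(sample_sheet = sample_sheet, edges_path = edges_path,
              gene_sets_path = gene_sets_path, out_dir = out_dir,
              control_bait = control_bait,
              max_control_unique = as.integer(max_control_unique),
              min_ratio = min_ratio, min_score = min_score,
              strategy = match.arg(strategy),
              aggregate = match.arg(aggregate),
              network_cutoff = network_cutoff,
              neg_log10_threshold = neg_log10_threshold,
              seed = as.integer(seed), quiet = isTRUE(quiet))
  if (cfg$network_cutoff < 0 || cfg$network_cutoff > 1)
    validation_error("network_cutoff must lie in [0, 1]")
  if (cfg$neg_log10_threshold < 0)
    validation_error("neg_log10_threshold must be nonnegative")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Any field of [pipeline_config()] may appear; unknown fields are an error.
#'
#' @param path JSON file path.
#' @param overrides named list of values taking precedence over the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) io_error(sprintf("config file not found: '%s'", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    validation_error(sprintf("unknown config field(s): %s",
                             paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[trapint] ", fmt), ...))
}

read_sample_sheet <- function(path) {
  sheet <- read_delim_auto(path)
  need <- c("path", "sample_id", "bait", "condition", "replicate")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    format_error(sprintf("sample sheet lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  if (!all(sheet$condition %in% valid_conditions))
    validation_error("sample sheet condition must be trap/reference/control")
  sheet$path <- ifelse(grepl("^(/|[A-Za-z]:)", sheet$path), sheet$path,
                       file.path(dirname(path), sheet$path))
  sheet
}

#' Run the full pipeline
#'
#' Executes ingest, replicate aggregation, the filtering cascade, enrichment
#' scoring, prioritisation, bait comparison (when two or more non-control
#' baits are present), network construction and gene-set
#' over-representation, writing every artifact plus a JSON run manifest to
#' `out_dir`. Identical config and inputs yield identical artifacts.
#'
#' @param config a `pipeline_config` or path to a JSON config file.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$sample_sheet, config$edges_path, config$gene_sets_path))
    if (!is.null(p) && !file.exists(p))
      io_error(sprintf("input path does not exist: '%s'", p))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  q <- config$quiet
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("trapint")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  note <- function(stage, info) manifest$stages[[stage]] <<- info

  sheet <- read_sample_sheet(config$sample_sheet)
  log_stage(q, "ingest: %d samples from %s", nrow(sheet), config$sample_sheet)
  tables <- lapply(seq_len(nrow(sheet)), function(i)
    read_identifications(sheet$path[i], sample_id = sheet$sample_id[i],
                         bait = sheet$bait[i], condition = sheet$condition[i],
                         replicate = sheet$replicate[i]))
  note("ingest", list(n_samples = length(tables),
                      rows = vapply(tables, function(t) nrow(t$records), 0L)))

  baits <- setdiff(unique(sheet$bait), config$control_bait)
  pooled <- list()
  for (b in baits) {
    for (cond in c("trap", "reference")) {
      idx <- which(sheet$bait == b & sheet$condition == cond)
      if (!length(idx))
        validation_error(sprintf("no %s sample for bait '%s'", cond, b))
      pooled[[b]][[cond]] <- aggregate_replicates(tables[idx],
                                                  method = config$aggregate)
    }
  }
  ctrl_idx <- which(sheet$bait == config$control_bait)
  control <- if (length(ctrl_idx))
    aggregate_replicates(tables[ctrl_idx], method = config$aggregate)
  else NULL

  prioritized <- list()
  enrichments <- list()
  for (b in baits) {
    trap <- drop_single_peptide(pooled[[b]]$trap)
    ref <- drop_single_peptide(pooled[[b]]$reference)
    if (!is.null(control)) {
      trap <- subtract_background(trap, control, config$max_control_unique)
      ref <- subtract_background(ref, control, config$max_control_unique)
    }
    rows_in <- nrow(trap$records)
    rows_removed <- sum(nzchar(trap$records$filter_flags))
    enr <- build_enrichment(trap, ref)
    pri <- prioritize(enr, min_ratio = config$min_ratio,
                      min_score = config$min_score,
                      strategy = config$strategy)
    write_results(enr, file.path(config$out_dir,
                                 sprintf("enrichment_%s.tsv", b)))
    write_results(pri, file.path(config$out_dir,
                                 sprintf("prioritized_%s.tsv", b)))
    prioritized[[b]] <- pri
    enrichments[[b]] <- enr
    log_stage(q, "bait %s: %d rows in, %d flagged, %d survivors, %d prioritized",
              b, rows_in, rows_removed, rows_in - rows_removed, nrow(pri))
    note(paste0("filter_", b),
         list(rows_in = rows_in, rows_removed = rows_removed,
              rows_out = rows_in - rows_removed, prioritized = nrow(pri)))
  }

  if (length(baits) >= 2L) {
    bb <- sort(baits)[1:2]
    diff <- compare_baits(enrichments[[bb[1]]], enrichments[[bb[2]]])
    write_results(diff, file.path(config$out_dir,
                                  sprintf("differential_%s_vs_%s.tsv",
                                          bb[1], bb[2])))
    note("compare_baits", list(baits = bb, rows_out = nrow(diff)))
    log_stage(q, "compare_baits: %s vs %s, %d proteins", bb[1], bb[2],
              nrow(diff))
  }

  hits <- unique(unlist(lapply(prioritized, function(p)
    p$gene_symbol[nzchar(p$gene_symbol)])))
  n_dropped <- sum(vapply(prioritized, function(p)
    sum(!nzchar(p$gene_symbol)), 0L))
  if (n_dropped > 0)
    log_stage(q, "%d prioritized protein(s) lack a gene symbol; excluded from network/over-representation",
              n_dropped)

  if (!is.null(config$edges_path)) {
    edges <- read_edge_scores(config$edges_path)
    graph <- build_network(hits, edges, cutoff = config$network_cutoff)
    write_results(graph, file.path(config$out_dir, "network.tsv"))
    note("network", list(n_hits = length(hits),
                         n_nodes = igraph::vcount(graph),
                         n_edges = igraph::ecount(graph)))
    log_stage(q, "network: %d nodes, %d edges at cutoff %.2f",
              igraph::vcount(graph), igraph::ecount(graph),
              config$network_cutoff)
  }

  if (!is.null(config$gene_sets_path)) {
    sets <- read_gene_sets(config$gene_sets_path)
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
    res <- fisher_enrichment(intersect(hits, universe), sets,
                             universe = universe)
    kept <- filter_terms(res, config$neg_log10_threshold)
    write_results(res, file.path(config$out_dir, "gene_sets_all.tsv"))
    write_results(kept, file.path(config$out_dir, "gene_sets_filtered.tsv"))
    note("gene_sets", list(n_sets = length(sets), n_tested = nrow(res),
                           n_kept = nrow(kept)))
    log_stage(q, "over-representation: %d sets tested, %d pass -log10(p) >= %.2f",
              nrow(res), nrow(kept), config$neg_log10_threshold)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a complete synthetic toy experiment directory
#'
#' Materialises one simulated trap/reference/control experiment (plus a
#' second, non-enriched bait standing in for a trapping-deficient mutant), a
#' matching synthetic interaction edge list and GMT collection, FRAP traces
#' for two conditions, a viability grid, a sample sheet and a ready-to-run
#' pipeline config — everything [run_pipeline()] and the assay functions
#' need.
#'
#' @param dir target directory (created).
#' @param cfg a [sim_config()].
#' @return The directory path, invisibly.
#' @export
write_fixture_experiment <- function(dir, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim_wt <- simulate_interactome(cfg)
  cfg_mut <- sim_config(seed = derive_seed(cfg$seed, 77L),
                        n_background = cfg$n_background, n_spiked = 0L,
                        lambda_bg = cfg$lambda_bg, fold = 1,
                        n_bead_binders = cfg$n_bead_binders,
                        dropout_ref = cfg$dropout_ref,
                        frap = cfg$frap, viability = cfg$viability)
  sim_mut <- simulate_interactome(cfg_mut)
  files <- c(wt_trap = "wt_trap.tsv", wt_ref = "wt_ref.tsv",
             mut_trap = "mut_trap.tsv", mut_ref = "mut_ref.tsv",
             control = "control.tsv")
  write_results(sim_wt$trap, file.path(dir, files["wt_trap"]))
  write_results(sim_wt$ref, file.path(dir, files["wt_ref"]))
  mt <- sim_mut$trap; mt$bait <- "mutant"; mt$sample_id <- "sim_mut_trap"
  mr <- sim_mut$ref; mr$bait <- "mutant"; mr$sample_id <- "sim_mut_ref"
  write_results(mt, file.path(dir, files["mut_trap"]))
  write_results(mr, file.path(dir, files["mut_ref"]))
  write_results(sim_wt$control, file.path(dir, files["control"]))
  sheet <- data.frame(
    path = unname(files),
    sample_id = c("wt_trap", "wt_ref", "mut_trap", "mut_ref", "control"),
    bait = c("wt", "wt", "mutant", "mutant", "parental"),
    condition = c("trap", "reference", "trap", "reference", "control"),
    replicate = 1L)
  write_tsv(sheet, file.path(dir, "samples.tsv"))

  # synthetic edges: a clique-ish core among spiked symbols at high scores,
  # plus background pairs straddling the 0.7 cutoff
  set.seed(derive_seed(cfg$seed, 91L))
  spk_sym <- paste0("G", sim_wt$truth$spiked)
  bg_sym <- paste0("G", sprintf("BG%05d", seq_len(min(cfg$n_background, 100))))
  edge_rows <- list()
  if (length(spk_sym) >= 2) {
    pairs <- utils::combn(spk_sym, 2)
    take <- sample.int(ncol(pairs), min(ncol(pairs), 4 * length(spk_sym)))
    edge_rows$spiked <- data.frame(symbol_a = pairs[1, take],
                                   symbol_b = pairs[2, take],
                                   score = round(stats::runif(length(take), 0.7, 0.99), 3))
  }
  if (length(bg_sym) >= 2) {
    pairs <- utils::combn(bg_sym, 2)
    take <- sample.int(ncol(pairs), min(ncol(pairs), 200))
    edge_rows$background <- data.frame(symbol_a = pairs[1, take],
                                       symbol_b = pairs[2, take],
                                       score = round(stats::runif(length(take), 0.15, 0.9), 3))
  }
  write_tsv(do.call(rbind, edge_rows), file.path(dir, "edges.tsv"))

  # synthetic gene sets: one enriched in spiked symbols, the rest background
  universe <- c(spk_sym, bg_sym)
  gmt <- c(
    paste(c("SPIKED_PATHWAY", "synthetic set enriched in spiked interactors",
            sample(spk_sym, max(2, round(length(spk_sym) * 0.6)))),
          collapse = "\t"),
    vapply(1:5, function(i)
      paste(c(sprintf("RANDOM_SET_%d", i), "synthetic background set",
              sample(universe, 20)), collapse = "\t"), ""))
  writeLines(gmt, file.path(dir, "sets.gmt"))

  frap_a <- simulate_frap(cfg)
  frap_b <- simulate_frap(sim_config(seed = derive_seed(cfg$seed, 5L),
                                     frap = utils::modifyList(cfg$frap,
                                       list(t_half = cfg$frap$t_half * 1.6))))
  write_frap_traces(frap_a$traces, file.path(dir, "frap_condition_a.tsv"))
  write_frap_traces(frap_b$traces, file.path(dir, "frap_condition_b.tsv"))
  via <- simulate_viability(cfg)
  write_tsv(via$long, file.path(dir, "viability.tsv"))

  config <- pipeline_config(sample_sheet = file.path(dir, "samples.tsv"),
                            edges_path = file.path(dir, "edges.tsv"),
                            gene_sets_path = file.path(dir, "sets.gmt"),
                            out_dir = file.path(dir, "out"),
                            seed = cfg$seed)
  cfg_list <- unclass(config)
  jsonlite::write_json(cfg_list[!vapply(cfg_list, is.null, TRUE)],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
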