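# Ingest and serialisation of every external format the pipeline touches:
# protein identification tables, GMT gene sets, weighted edge lists, and
# round-trippable TSV/JSON result artifacts.

#' Default column mapping for identification tables
#'
#' Maps the five consumed record fields to the column names of the canonical
#' export header (`accession`, `gene_symbol`, `unique_peptides`, `psms`,
#' `ms_score`). Supply a modified copy to [read_identifications()] to absorb
#' other search-engine export layouts (e.g. a Proteome Discoverer protein
#' table).
#'
#' @return Named character vector: field name -> column name in the file.
#' @export
default_dialect <- function() {
  c(accession       = "accession",
    gene_symbol     = "gene_symbol",
    unique_peptides = "unique_peptides",
    psms            = "psms",
    ms_score        = "ms_score")
}

valid_conditions <- c("trap", "reference", "control")

#' Construct a validated identification table
#'
#' An identification table holds one sample's protein identification evidence:
#' one row per protein with its accession, gene symbol, unique-peptide count,
#' PSM (peptide spectrum match) count and search-engine protein score, plus
#' sample metadata. PSMs serve as the protein-abundance proxy throughout the
#' pipeline.
#'
#' @param records data.frame with columns `accession`, `gene_symbol`,
#'   `unique_peptides`, `psms`, `ms_score`. Gene symbols are uppercased;
#'   missing symbols become `""`.
#' @param sample_id sample identifier string.
#' @param bait bait label (e.g. `"wt"`, `"mutant"`, `"apex_wt"`, `"parental"`).
#' @param condition one of `"trap"` (damage + trapping drug), `"reference"`
#'   (damage alone) or `"control"` (bait-negative background sample).
#' @param replicate positive integer replicate index.
#' @return An object of class `ident_table`.
#' @export
identification_table <- function(records, sample_id, bait, condition,
                                 replicate = 1L) {
  if (length(condition) != 1L || !condition %in% valid_conditions)
    validation_error(sprintf("condition must be one of: %s",
                             paste(valid_conditions, collapse = ", ")))
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    validation_error("sample_id must be a non-empty string")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    validation_error("replicate must be a positive integer")
  records <- validate_records(records)
  structure(
    list(sample_id = sample_id, bait = as.character(bait),
         condition = condition, replicate = replicate, records = records),
    class = "ident_table")
}

record_columns <- c("accession", "gene_symbol", "unique_peptides", "psms",
                    "ms_score")

validate_records <- function(records) {
  if (!is.data.frame(records))
    validation_error("records must be a data.frame")
  missing <- setdiff(record_columns, names(records))
  if (length(missing))
    format_error(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  records <- records[record_columns]
  records$accession <- as.character(records$accession)
  if (anyNA(records$accession) || any(!nzchar(records$accession)))
    validation_error(sprintf(
      "empty accession at row(s): %s",
      paste(which(is.na(records$accession) | !nzchar(records$accession)),
            collapse = ", ")))
  dup <- duplicated(records$accession)
  if (any(dup))
    validation_error(sprintf(
      "duplicate accession(s): %s",
      paste(unique(records$accession[dup]), collapse = ", ")))
  records$gene_symbol <- clean_symbols(records$gene_symbol)
  for (col in c("unique_peptides", "psms")) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(!is_count(v))
    if (length(bad))
      validation_error(sprintf(
        "column '%s' must hold nonnegative integers; bad row(s): %s",
        col, paste(bad, collapse = ", ")))
    records[[col]] <- as.integer(round(v))
  }
  score <- suppressWarnings(as.numeric(records$ms_score))
  bad <- which(is.na(score) | score < 0)
  if (length(bad))
    validation_error(sprintf(
      "column 'ms_score' must be nonnegative numeric; bad row(s): %s",
      paste(bad, collapse = ", ")))
  records$ms_score <- score
  incons <- which(records$psms >= 1L & records$unique_peptides < 1L)
  if (length(incons))
    validation_error(sprintf(
      "unique_peptides must be >= 1 when psms >= 1; bad row(s): %s",
      paste(incons, collapse = ", ")))
  if (is.null(records$filter_flags))
    records$filter_flags <- rep("", nrow(records))
  rownames(records) <- NULL
  records
}

#' @export
print.ident_table <- function(x, ...) {
  cat(sprintf("<ident_table> sample '%s' (bait %s, %s, rep %d): %d proteins\n",
              x$sample_id, x$bait, x$condition, x$replicate,
              nrow(x$records)))
  flagged <- sum(nzchar(x$records$filter_flags))
  if (flagged > 0) cat(sprintf("  %d record(s) flagged by filters\n", flagged))
  invisible(x)
}

#' Read a protein identification table from delimited text
#'
#' Accepts tab- or comma-delimited text with a header row. Column names are
#' translated through `dialect`; the five consumed fields must all be present.
#' Sample metadata comes from the arguments, or from `#key=value` comment
#' lines at the top of the file (as written by [write_results()]).
#'
#' @param path file path.
#' @param dialect named character vector mapping the five field names to the
#'   file's column names; see [default_dialect()].
#' @param sample_id,bait,condition,replicate sample metadata; when `NULL`,
#'   taken from `#key=value` header comments, with fallbacks
#'   `sample_id = basename(path)`, `bait = "unknown"`, `replicate = 1`.
#'   `condition` must be resolvable.
#' @return An `ident_table`.
#' @export
read_identifications <- function(path, dialect = default_dialect(),
                                 sample_id = NULL, bait = NULL,
                                 condition = NULL, replicate = NULL) {
  if (!file.exists(path)) io_error(sprintf("file not found: '%s'", path))
  meta <- read_meta_comments(path)
  df <- read_delim_auto(path)
  missing <- dialect[!dialect %in% names(df)]
  if (length(missing))
    format_error(sprintf("missing column(s) in '%s': %s", path,
                         paste(missing, collapse = ", ")))
  records <- df[unname(dialect)]
  names(records) <- names(dialect)
  sample_id <- sample_id %||% meta$sample_id %||% basename(path)
  bait      <- bait      %||% meta$bait      %||% "unknown"
  condition <- condition %||% meta$condition
  if (is.null(condition))
    validation_error("condition not supplied and not found in file header")
  replicate <- replicate %||% meta$replicate %||% 1L
  identification_table(records, sample_id = sample_id, bait = bait,
                       condition = condition,
                       replicate = as.integer(replicate))
}

read_meta_comments <- function(path) {
  lines <- readLines(path, n = 10L)
  meta_lines <- grep("^#[A-Za-z_]+=", lines, value = TRUE)
  if (!length(meta_lines)) return(list())
  kv <- sub("^#", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a gene-set collection in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are uppercased and de-duplicated; sets left empty are dropped with
#' a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      format_error(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                           i, length(fields)))
    members <- unique(clean_symbols(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning(sprintf("gene set '%s' (line %d) has no members; dropped",
                      fields[[1]], i))
      next
    }
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' Read a weighted interaction edge list
#'
#' Expects delimited text whose first three columns are two gene symbols and a
#' combined interaction score, in STRING-export style. Scores may be on
#' \[0, 1\] or on STRING's integer \[0, 1000\] scale; the latter is detected
#' (any score above 1, all integral) and normalised by division by 1000.
#' Self-edges are dropped and duplicate unordered pairs keep their maximum
#' score.
#'
#' @param path file path.
#' @return data.frame with columns `symbol_a`, `symbol_b`, `score` (in
#'   \[0, 1\]), rows sorted by symbol pair.
#' @export
read_edge_scores <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 3L)
    format_error(sprintf("edge file '%s' needs at least 3 columns", path))
  edges <- data.frame(symbol_a = clean_symbols(df[[1]]),
                      symbol_b = clean_symbols(df[[2]]),
                      score = suppressWarnings(as.numeric(df[[3]])),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$score))
    validation_error("non-numeric interaction score(s)")
  normalize_edge_scores(edges)
}

normalize_edge_scores <- function(edges) {
  s <- edges$score
  if (any(s < 0))
    validation_error("negative interaction score(s)")
  if (any(s > 1)) {
    # must then be the STRING integer scale for every row
    if (any(s > 1000) || any(abs(s - round(s)) > 1e-8))
      validation_error(
        "scores are neither all on [0,1] nor all integers on [0,1000]")
    s <- s / 1000
  }
  edges$score <- s
  edges <- edges[edges$symbol_a != edges$symbol_b, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$symbol_a, edges$symbol_b)
    b <- pmax(edges$symbol_a, edges$symbol_b)
    edges$symbol_a <- a
    edges$symbol_b <- b
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    edges <- data.frame(symbol_a = vapply(parts, `[`, "", 1L),
                        symbol_b = vapply(parts, `[`, "", 2L),
                        score = as.numeric(score),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$symbol_a, edges$symbol_b), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Write a pipeline product to disk
#'
#' Tabular products (identification tables, enrichment records, differential
#' rows, gene-set results, data.frames) are written as TSV with a fixed,
#' documented column order; identification tables carry their sample metadata
#' in `#key=value` header comments so [read_identifications()] round-trips
#' them exactly. Fit and graph summaries are written as JSON.
#'
#' @param x a pipeline product.
#' @param path output file path.
#' @param ... passed to methods.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

write_tsv <- function(df, path, header_comments = character(0)) {
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    io_error(sprintf("cannot open '%s' for writing: %s", path,
                     conditionMessage(e))))
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("#", names(header_comments), "=",
                      unlist(header_comments)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
write_results.ident_table <- function(x, path, ...) {
  meta <- c(sample_id = x$sample_id, bait = x$bait, condition = x$condition,
            replicate = as.character(x$replicate))
  write_tsv(x$records, path, header_comments = meta)
}

#' @export
write_results.data.frame <- function(x, path, ...) {
  df <- x
  df[] <- lapply(df, function(col) if (is.numeric(col)) col else col)
  write_tsv(df, path)
}

#' @export
write_results.igraph <- function(x, path, ...) {
  el <- network_edge_table(x)
  write_tsv(el, path)
  summary_path <- sub("\\.[^.]+$", "", path)
  summary_path <- paste0(summary_path, ".summary.json")
  jsonlite::write_json(network_summary(x), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_results.frap_fit <- function(x, path, ...) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_results.f_test_result <- function(x, path, ...) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_results.bliss_result <- function(x, path, ...) {
  long <- bliss_long(x)
  write_tsv(long, path)
  invisible(path)
}

#' @export
write_results.default <- function(x, path, ...) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
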