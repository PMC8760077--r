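# Ingest, validation and round-trip serialisation.

test_that("identification tables round-trip through delimited text", {
  recs <- make_records(c("P1", "P2", "P3"), psms = c(4L, 9L, 0L),
                       unique_peptides = c(2L, 5L, 1L),
                       ms_score = c(120.5, 300, 0))
  recs$gene_symbol[3] <- NA   # missing symbol becomes ""
  tab <- make_table(recs, condition = "trap", bait = "wt", sample_id = "wt_t1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, path)
  back <- read_identifications(path)
  expect_identical(back$records, tab$records)
  expect_identical(back[c("sample_id", "bait", "condition", "replicate")],
                   tab[c("sample_id", "bait", "condition", "replicate")])
})

test_that("comma- and tab-delimited inputs yield identical tables", {
  recs <- make_records(c("A1", "B2"), psms = c(3L, 7L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(recs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(recs, csv, sep = ",", quote = FALSE, row.names = FALSE)
  t1 <- read_identifications(tsv, condition = "trap", sample_id = "s")
  t2 <- read_identifications(csv, condition = "trap", sample_id = "s")
  expect_identical(t1$records, t2$records)
})

test_that("malformed identification tables are rejected with location info", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # header lacking the PSM column
  utils::write.table(make_records("P1")[-4], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_identifications(path, condition = "trap"),
               "psms", class = "trapint_format_error")
  # duplicated accession
  utils::write.table(make_records(c("P1", "P1")), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_identifications(path, condition = "trap"),
               "duplicate accession", class = "trapint_validation_error")
  # negative / non-integer counts carry the row number
  bad <- make_records(c("P1", "P2"))
  bad$psms <- c(5, -1)
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_identifications(path, condition = "trap"),
               "row\\(s\\): 2", class = "trapint_validation_error")
  bad$psms <- c(5, 2.5)
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_identifications(path, condition = "trap"), "psms")
})

test_that("record invariants are enforced at construction", {
  expect_error(make_table(make_records("P1", psms = 3L, unique_peptides = 0L)),
               "unique_peptides", class = "trapint_validation_error")
  expect_error(make_table(make_records("")), "accession")
  expect_error(identification_table(make_records("P1"), "s", "wt", "banana"),
               "condition")
})

test_that("GMT parsing uppercases, de-duplicates and drops empty sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SetA\tdesc\tg1\tg2\tg2",
               "SetC\tdesc\t\t",
               "SetD\tdesc\tx1"), path)
  expect_warning(sets <- read_gene_sets(path), "SetC")
  expect_identical(sets, list(SetA = c("G1", "G2"), SetD = "X1"))

  writeLines(character(0), path)
  expect_length(read_gene_sets(path), 0)

  writeLines("SetB\tdesc", path)
  expect_error(read_gene_sets(path), "line 1",
               class = "trapint_format_error")
})

test_that("edge scores normalise, deduplicate and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol_a\tsymbol_b\tscore",
               "A\tB\t700", "B\tA\t650", "A\tA\t900", "B\tC\t450"), path)
  edges <- read_edge_scores(path)
  expect_identical(edges$symbol_a, c("A", "B"))
  expect_identical(edges$symbol_b, c("B", "C"))
  expect_equal(edges$score, c(0.70, 0.45))

  # a score above 1 among otherwise [0,1] scores fits neither scale
  writeLines(c("symbol_a\tsymbol_b\tscore",
               "A\tB\t1.2", "B\tC\t0.5"), path)
  expect_error(read_edge_scores(path), "neither",
               class = "trapint_validation_error")
  # plain [0,1] scores pass through untouched
  writeLines(c("symbol_a\tsymbol_b\tscore", "A\tB\t0.8"), path)
  expect_equal(read_edge_scores(path)$score, 0.8)
})

test_that("tabular write_results round-trips numeric content", {
  df <- data.frame(set_name = c("A", "B"), p_value = c(0.012, 0.4),
                   overlap = c(3L, 1L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(df, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, df)
  expect_error(write_results(df, file.path(tempdir(), "no", "such", "dir", "x.tsv")),
               class = "trapint_io_error")
})
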