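# Internal helpers: classed conditions and small shared utilities.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "trapint_error"), call = call))
}

format_error <- function(msg) abort(msg, "trapint_format_error", sys.call(-1))

validation_error <- function(msg) abort(msg, "trapint_validation_error", sys.call(-1))

io_error <- function(msg) abort(msg, "trapint_io_error", sys.call(-1))

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Uppercase gene symbols, mapping NA to "" so the column is always character.
clean_symbols <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  toupper(trimws(x))
}

# Sniff the delimiter of a delimited text file from the first
# non-comment line: tab wins if present, otherwise comma.
sniff_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return("\t")
  if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
}

read_delim_auto <- function(path, comment.char = "#") {
  if (!file.exists(path)) io_error(sprintf("file not found: '%s'", path))
  utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                    quote = "", comment.char = comment.char,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}
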