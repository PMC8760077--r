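# Filtering cascade and pseudocounted PSM enrichment for trapped-bait
# interaction proteomics.
#
# The cascade removes weak identifications (single peptide), subtracts
# bait-negative background (proteins identified with more than
# `max_control_unique` unique peptides in the control sample), then scores
# each surviving protein by the trap/reference PSM ratio, substituting a
# pseudocount of 1 when the protein was not detected in the reference.

FLAG_SINGLE  <- "single_peptide"
FLAG_CONTROL <- "control_background"

add_flag <- function(flags, where, flag) {
  flags[where] <- ifelse(nzchar(flags[where]),
                         paste(flags[where], flag, sep = ","),
                         flag)
  flags
}

apply_filter <- function(table, drop_idx, flag, mode) {
  mode <- match.arg(mode, c("flag", "remove"))
  if (mode == "remove") {
    table$records <- table$records[!drop_idx, , drop = FALSE]
    rownames(table$records) <- NULL
  } else {
    already <- grepl(flag, table$records$filter_flags, fixed = TRUE)
    table$records$filter_flags <-
      add_flag(table$records$filter_flags, drop_idx & !already, flag)
  }
  table
}

#' Remove single-peptide identifications
#'
#' Proteins identified with a single unique peptide are unreliable and are
#' removed (or, in the default audit mode, flagged `single_peptide` and
#' excluded from all downstream scoring). Idempotent.
#'
#' @param table an `ident_table`.
#' @param mode `"flag"` (default; annotate and keep the row) or `"remove"`.
#' @return The filtered `ident_table`.
#' @export
drop_single_peptide <- function(table, mode = c("flag", "remove")) {
  stopifnot(inherits(table, "ident_table"))
  drop <- table$records$unique_peptides <= 1L
  apply_filter(table, drop, FLAG_SINGLE, match.arg(mode))
}

#' Subtract bait-negative background
#'
#' Any protein identified in the bait-negative control sample with more than
#' `max_control_unique` unique peptides is treated as background (bead binder
#' or non-specific capture) and removed from `table`. Proteins absent from
#' the control, or present with at most `max_control_unique` unique peptides,
#' are retained.
#'
#' @param table an `ident_table` to filter.
#' @param control the designated negative-control `ident_table`.
#' @param max_control_unique highest tolerated unique-peptide count in the
#'   control (default 2, i.e. the ">2 unique peptides" removal rule).
#' @param mode `"flag"` (default) or `"remove"`.
#' @return The filtered `ident_table`.
#' @export
subtract_background <- function(table, control, max_control_unique = 2L,
                                mode = c("flag", "remove")) {
  stopifnot(inherits(table, "ident_table"), inherits(control, "ident_table"))
  if (nrow(control$records) == 0L) {
    warning("control table is empty; no background subtracted")
    return(table)
  }
  ctrl_up <- stats::setNames(control$records$unique_peptides,
                             control$records$accession)
  up <- ctrl_up[table$records$accession]
  drop <- !is.na(up) & up > max_control_unique
  apply_filter(table, drop, FLAG_CONTROL, match.arg(mode))
}

surviving_records <- function(table) {
  table$records[!nzchar(table$records$filter_flags), , drop = FALSE]
}

#' Combine replicate identification tables
#'
#' Per-accession PSM and unique-peptide counts are combined across replicates
#' (`sum` by default, which preserves integer counts; `mean_rounded` rounds
#' the per-replicate mean, treating absence as zero). The protein score is
#' combined by maximum. All tables must share bait and condition.
#'
#' @param tables list of `ident_table`s from the same bait and condition.
#' @param method `"sum"` (default) or `"mean_rounded"`.
#' @return A single pooled `ident_table` (replicate index 1).
#' @export
aggregate_replicates <- function(tables, method = c("sum", "mean_rounded")) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "ident_table")))
  if (length(tables) == 1L) return(tables[[1L]])
  baits <- unique(vapply(tables, `[[`, "", "bait"))
  conds <- unique(vapply(tables, `[[`, "", "condition"))
  if (length(baits) != 1L || length(conds) != 1L)
    validation_error("aggregate_replicates requires a single bait and condition")
  all_acc <- sort(unique(unlist(lapply(tables, function(t)
    t$records$accession))))
  n <- length(all_acc)
  psms <- up <- matrix(0, nrow = n, ncol = length(tables),
                       dimnames = list(all_acc, NULL))
  score <- matrix(0, nrow = n, ncol = length(tables),
                  dimnames = list(all_acc, NULL))
  symbol <- stats::setNames(character(n), all_acc)
  for (j in seq_along(tables)) {
    r <- tables[[j]]$records
    psms[r$accession, j]  <- r$psms
    up[r$accession, j]    <- r$unique_peptides
    score[r$accession, j] <- r$ms_score
    pick <- nzchar(r$gene_symbol)
    symbol[r$accession[pick]] <- r$gene_symbol[pick]
  }
  comb <- switch(method,
    sum          = function(m) as.integer(rowSums(m)),
    mean_rounded = function(m) as.integer(round(rowMeans(m))))
  records <- data.frame(
    accession       = all_acc,
    gene_symbol     = unname(symbol),
    unique_peptides = comb(up),
    psms            = comb(psms),
    ms_score        = apply(score, 1L, max),
    stringsAsFactors = FALSE)
  # rounding can yield psms >= 1 with unique_peptides 0; restore the invariant
  records$unique_peptides[records$psms >= 1L & records$unique_peptides < 1L] <- 1L
  records <- records[records$psms > 0L | records$unique_peptides > 0L, ,
                     drop = FALSE]
  identification_table(
    records,
    sample_id = paste(vapply(tables, `[[`, "", "sample_id"), collapse = "+"),
    bait = baits, condition = conds, replicate = 1L)
}

#' Pseudocounted trap/reference PSM enrichment ratio
#'
#' Returns `psm_trap / psm_ref` when the protein was detected in the
#' reference sample with a positive PSM count. When the reference detection
#' is absent (`NA`) or zero, a pseudocount of 1 is substituted in the
#' denominator so the ratio stays meaningful. A protein undetected in the
#' trap sample gets ratio 0.
#'
#' @param psm_trap nonnegative integer vector, PSMs under trapping.
#' @param psm_ref nonnegative integer vector, PSMs in the reference; `NA`
#'   marks absence.
#' @return Numeric vector of ratios.
#' @export
enrichment_ratio <- function(psm_trap, psm_ref) {
  if (length(psm_ref) == 1L && length(psm_trap) > 1L)
    psm_ref <- rep(psm_ref, length(psm_trap))
  stopifnot(length(psm_trap) == length(psm_ref))
  if (any(is.na(psm_trap) & is.na(psm_ref)))
    validation_error("enrichment_ratio undefined when both PSM values are absent")
  if (any(!is.na(psm_trap) & psm_trap < 0) ||
      any(!is.na(psm_ref) & psm_ref < 0))
    validation_error("PSM counts must be nonnegative")
  denom <- ifelse(is.na(psm_ref) | psm_ref == 0, 1, psm_ref)
  as.numeric(psm_trap) / denom
}

#' Build per-protein enrichment records
#'
#' One record per (unflagged) protein in the trap sample, scored by
#' [enrichment_ratio()] against the reference sample; the protein score is
#' taken from the trap sample. Proteins detected only in the reference are
#' never assigned a ratio; they are returned in the `"reference_only"`
#' attribute.
#'
#' @param trap,ref `ident_table`s for the trapping and reference conditions,
#'   already passed through the filtering cascade (flagged rows are ignored).
#' @return data.frame of class `enrichment_records` with columns `accession`,
#'   `gene_symbol`, `psm_trap`, `psm_ref` (`NA` = absent), `ratio`,
#'   `ms_score`, `filter_flags`; attribute `reference_only` holds the
#'   reference-only records.
#' @export
build_enrichment <- function(trap, ref) {
  stopifnot(inherits(trap, "ident_table"), inherits(ref, "ident_table"))
  tr <- surviving_records(trap)
  rf <- surviving_records(ref)
  ref_psm <- stats::setNames(rf$psms, rf$accession)
  psm_ref <- unname(ref_psm[tr$accession])   # NA where absent from reference
  out <- data.frame(
    accession    = tr$accession,
    gene_symbol  = tr$gene_symbol,
    psm_trap     = tr$psms,
    psm_ref      = as.integer(psm_ref),
    ratio        = if (nrow(tr)) enrichment_ratio(tr$psms, psm_ref) else numeric(0),
    ms_score     = tr$ms_score,
    filter_flags = rep("", nrow(tr)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  attr(out, "reference_only") <-
    rf[!rf$accession %in% tr$accession, , drop = FALSE]
  out
}

#' Prioritise enrichment records by ratio and protein score
#'
#' Keeps records with `ratio >= min_ratio` and `ms_score >= min_score`, then
#' ranks by `(ratio, ms_score)` under `"ratio_first"` or `(ms_score, ratio)`
#' under `"score_first"` (both descending), breaking ties by accession.
#'
#' `"ratio_first"` reflects prioritising trap-specific enrichment (the
#' two-bait immunoprecipitation arm); `"score_first"` prioritises abundant,
#' high-stoichiometry interactors (the proximity-labelling arm, where no
#' trapping-deficient control bait exists).
#'
#' @param records an `enrichment_records` data.frame.
#' @param min_ratio minimum enrichment ratio (default 2).
#' @param min_score minimum protein score (default 0).
#' @param strategy `"ratio_first"` (default) or `"score_first"`.
#' @return The surviving records, ranked, with a leading `rank` column.
#' @export
prioritize <- function(records, min_ratio = 2, min_score = 0,
                       strategy = c("ratio_first", "score_first")) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(records))
  keep <- records[!nzchar(records$filter_flags) &
                    records$ratio >= min_ratio &
                    records$ms_score >= min_score, , drop = FALSE]
  ord <- if (strategy == "ratio_first") {
    order(-keep$ratio, -keep$ms_score, keep$accession)
  } else {
    order(-keep$ms_score, -keep$ratio, keep$accession)
  }
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  out <- cbind(rank = seq_len(nrow(keep)), keep)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Compare enrichment between two baits
#'
#' Outer join of two enrichment-record lists on accession, e.g. wild-type
#' versus trapping-deficient bait. A protein detected in only one bait keeps
#' its ratio on that side and `NA` on the other (the "unidentified" case),
#' with presence flags set accordingly.
#'
#' @param wt,mut `enrichment_records` built under the same filter settings.
#' @return data.frame with columns `accession`, `gene_symbol`, `ratio_wt`,
#'   `ratio_mut`, `present_wt`, `present_mut`, sorted by accession.
#' @export
compare_baits <- function(wt, mut) {
  stopifnot(is.data.frame(wt), is.data.frame(mut))
  acc <- sort(unique(c(wt$accession, mut$accession)))
  iw <- match(acc, wt$accession)
  im <- match(acc, mut$accession)
  symbol <- ifelse(!is.na(iw), wt$gene_symbol[iw],
                   mut$gene_symbol[im])
  out <- data.frame(
    accession   = acc,
    gene_symbol = symbol,
    ratio_wt    = wt$ratio[iw],
    ratio_mut   = mut$ratio[im],
    present_wt  = !is.na(iw),
    present_mut = !is.na(im),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
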