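# Disposition of previously unplaced (chrUn) contigs after gap filling:
# placed into a gap, contained in pre-existing sequence, or still unplaced.
# The remainder is concatenated into a single record with N spacers.

#' Classify unplaced contigs against the patched assembly
#'
#' Each contig is run through [placement_filter()] on its alignments to the
#' patched assembly. Contigs that pass are `placed_in_gap` when the best
#' location overlaps any ledger fill interval by at least 1 bp, else
#' `contained`; contigs failing the filter are `unplaced`.
#'
#' @param contig_lens Named numeric vector of contig lengths.
#' @param blocks Alignment blocks of the contigs (query = contig name)
#'   against the patched (new-coordinate) assembly.
#' @param ledger The `patch_ledger` that produced the patched assembly.
#' @param prior_assignment Optional named character vector: contig ->
#'   previously assigned chromosome (NA when none).
#' @param min_q_frac,max_mismatch Placement thresholds (defaults 0.9, 0.02).
#' @return data.frame `contig`, `verdict`, `chrom`, `start`, `end`,
#'   `prior_assignment`.
#' @export
classify_chrun <- function(contig_lens, blocks, ledger, prior_assignment = NULL,
                           min_q_frac = 0.9, max_mismatch = 0.02) {
  fills <- ledger_fill_intervals(ledger)
  fills <- fills[fills$new_end > fills$new_start, , drop = FALSE]
  rows <- lapply(names(contig_lens), function(nm) {
    b <- blocks[blocks$query == nm, , drop = FALSE]
    pl <- placement_filter(b, contig_lens[[nm]], min_q_frac, max_mismatch)
    verdict <- "unplaced"; chrom <- NA_character_; s <- NA_real_; e <- NA_real_
    if (isTRUE(pl$placed)) {
      chrom <- pl$target; s <- pl$t_start; e <- pl$t_end
      f <- fills[fills$chrom == chrom, , drop = FALSE]
      in_gap <- any(f$new_start < e & f$new_end > s)
      verdict <- if (in_gap) "placed_in_gap" else "contained"
    }
    data.frame(contig = nm, verdict = verdict, chrom = chrom, start = s, end = e,
               prior_assignment = if (is.null(prior_assignment)) NA_character_
                                  else unname(prior_assignment[nm]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concatenate unplaced contigs into one record
#'
#' Joins the contigs in the given order, separated by `spacer_len` N's, and
#' returns a BED-style index locating each contig in the concatenated
#' sequence so the operation round-trips exactly.
#'
#' @param contigs Named character vector or `DNAStringSet` of contig
#'   sequences (at least one; duplicate names are an error).
#' @param spacer_len Spacer N-run length (default 100).
#' @param name Name of the concatenated record (default `"chrUn"`).
#' @return list `record` (named character of length 1), `index` (data.frame
#'   `chrom`, `start`, `end`, `contig`).
#' @export
concatenate_unplaced <- function(contigs, spacer_len = 100L, name = "chrUn") {
  if (methods::is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  fail_if(length(contigs) < 1L, "no contigs to concatenate")
  fail_if(anyDuplicated(names(contigs)) > 0, "duplicate contig names")
  lens <- nchar(contigs)
  starts <- cumsum(c(0, lens[-length(lens)] + spacer_len))
  seq <- paste(contigs, collapse = strrep("N", spacer_len))
  list(record = stats::setNames(seq, name),
       index = data.frame(chrom = name, start = starts, end = starts + lens,
                          contig = names(contigs), stringsAsFactors = FALSE))
}

#' Concordance of placements with prior chromosome assignments
#'
#' Among contigs that were placed and carry a prior assignment, the fraction
#' whose placement chromosome matches the prior one.
#'
#' @param dispositions Output of [classify_chrun()].
#' @return list `fraction` (NA with `defined = FALSE` when no contig
#'   qualifies), `pct` (one-decimal percent), `n_matching`, `n_total`,
#'   `defined`.
#' @export
assignment_concordance <- function(dispositions) {
  d <- dispositions[dispositions$verdict %in% c("placed_in_gap", "contained") &
                      !is.na(dispositions$prior_assignment), , drop = FALSE]
  if (nrow(d) == 0L)
    return(list(fraction = NA_real_, pct = NA_real_, n_matching = 0L,
                n_total = 0L, defined = FALSE))
  match_ok <- d$chrom == d$prior_assignment
  list(fraction = mean(match_ok), pct = round(100 * mean(match_ok), 1),
       n_matching = sum(match_ok), n_total = nrow(d), defined = TRUE)
}
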