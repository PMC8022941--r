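# Bookkeeping arithmetic shared by the gap-closing report: closure
# percentages, gap balance, placement fractions and contiguity fold change.
# These helpers exist so that every headline number in a run report is
# produced by one audited code path.

#' Percentage of gaps closed
#'
#' @param n_closed,n_total Gap counts.
#' @param digits Decimals in the percentage (default 1).
#' @return Percentage on the 0-100 scale.
#' @examples
#' pct_closed(10394, 13538)  # 76.8
#' @export
pct_closed <- function(n_closed, n_total, digits = 1) {
  fail_if(n_total <= 0, "n_total must be > 0")
  round(100 * n_closed / n_total, digits)
}

#' Gaps remaining after closure
#'
#' @param n_total,n_closed Gap counts.
#' @return `n_total - n_closed`.
#' @export
gaps_remaining <- function(n_total, n_closed) {
  fail_if(n_closed > n_total, "closed more gaps than existed")
  n_total - n_closed
}

#' Fraction as a one-decimal percentage
#'
#' @param numerator,denominator Counts.
#' @param digits Decimals (default 1).
#' @return Percentage on the 0-100 scale.
#' @export
pct_of <- function(numerator, denominator, digits = 1) {
  fail_if(denominator <= 0, "denominator must be > 0")
  round(100 * numerator / denominator, digits)
}

#' Stickleback chromosome lengths (printed reference table)
#'
#' The published per-chromosome lengths (bp) of the v4 reference assembly
#' and the Paxton Lake long-read assembly, shipped as a plain-text table.
#' Autosomes are every chromosome except chrXIX (the sex chromosome).
#'
#' @return data.frame `chrom`, `v4_reference`, `paxton_assembly`.
#' @export
stickleback_chrom_lengths <- function() {
  utils::read.table(system.file("extdata", "stickleback_chrom_lengths.tsv",
                                package = "gapweaver"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Column sums of a chromosome-length table
#'
#' @param tab data.frame as returned by [stickleback_chrom_lengths()].
#' @param autosomes_only Drop chrXIX before summing (default TRUE).
#' @return Named numeric vector of per-assembly total lengths in bp.
#' @export
chrom_length_totals <- function(tab, autosomes_only = TRUE) {
  if (autosomes_only) tab <- tab[tab$chrom != "chrXIX", , drop = FALSE]
  colSums(tab[, -1, drop = FALSE])
}
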