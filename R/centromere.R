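# Centromeric satellite analysis: locate tandem copies of a consensus
# monomer (the ~186 bp centromeric repeat unit) in assembled contigs,
# assign monomer-bearing contigs to a chromosome side of the annotated
# centromere gap, and estimate higher-order repeat (HOR) periodicity.

#' Find monomer copies in a contig
#'
#' Scans both strands for local matches to the consensus monomer allowing
#' mismatches and indels up to `1 - min_identity` of the monomer length,
#' keeps non-overlapping hits left to right, and reports per-hit identity
#' (matching positions / alignment columns against the consensus).
#'
#' @param contig_seq Contig sequence (character or DNAString).
#' @param consensus Consensus monomer (>= 50 bp).
#' @param min_identity Identity threshold in (0,1] (default 0.75).
#' @return list `hits` (data.frame `start`, `end` 0-based half-open,
#'   `strand`, `identity`), `monomer_count`, `array_span` (bp between first
#'   hit start and last hit end; 0 when no hit).
#' @export
find_monomers <- function(contig_seq, consensus, min_identity = 0.75) {
  consensus <- toupper(as.character(consensus))
  fail_if(nchar(consensus) < 50L, "consensus monomer must be >= 50 bp")
  subject <- Biostrings::DNAString(toupper(as.character(contig_seq)))
  max_mm <- floor((1 - min_identity) * nchar(consensus))
  scan_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mm, with.indels = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  hits <- rbind(scan_one(consensus, "+"),
                scan_one(revcomp_chr(consensus), "-"))
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(hits = data.frame(start = integer(), end = integer(),
                                  strand = character(), identity = numeric()),
                monomer_count = 0L, array_span = 0))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  # greedy non-overlapping selection, left to right
  keep <- logical(nrow(hits)); last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) { keep[i] <- TRUE; last_end <- hits$end[i] }
  }
  hits <- hits[keep, , drop = FALSE]
  cons_d <- Biostrings::DNAString(consensus)
  hits$identity <- vapply(seq_len(nrow(hits)), function(i) {
    frag <- subject[(hits$start[i] + 1L):hits$end[i]]
    if (hits$strand[i] == "-") frag <- Biostrings::reverseComplement(frag)
    aln <- Biostrings::pairwiseAlignment(frag, cons_d, type = "global")
    Biostrings::pid(aln) / 100
  }, numeric(1))
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, monomer_count = nrow(hits),
       array_span = if (nrow(hits)) max(hits$end) - min(hits$start) else 0)
}

#' Assign a monomer-bearing contig to a chromosome side
#'
#' A contig is retained when more than `min_unique` bp of it aligns uniquely
#' (primary alignments) to the periphery of exactly one chromosome's
#' centromere gap: `left_of_gap`, `right_of_gap`, or `spanning` when it
#' anchors uniquely on both sides of one centromere gap.
#'
#' @param blocks Primary alignment blocks of one contig against the
#'   assembly.
#' @param cen_gaps data.frame `chrom`, `start`, `end`: the annotated
#'   centromere gap per chromosome (0-based half-open).
#' @param min_unique Unique-anchor threshold in bp (default 10000, strict).
#' @param side_window Peripheral window on each side of the gap in bp
#'   (default 100000).
#' @return list `chrom`, `side` ("left_of_gap"/"right_of_gap"/"spanning");
#'   or NULL when the contig anchors nowhere or ambiguously across
#'   chromosomes.
#' @export
assign_centromere <- function(blocks, cen_gaps, min_unique = 10000,
                              side_window = 100000) {
  blocks <- blocks[blocks$is_primary, , drop = FALSE]
  if (nrow(blocks) == 0L) return(NULL)
  per_chrom <- list()
  for (i in seq_len(nrow(cen_gaps))) {
    nm <- cen_gaps$chrom[i]
    left <- unique_anchor_span(blocks, nm,
                               cen_gaps$start[i] - side_window, cen_gaps$start[i])
    right <- unique_anchor_span(blocks, nm,
                                cen_gaps$end[i], cen_gaps$end[i] + side_window)
    sides <- c(left = left > min_unique, right = right > min_unique)
    if (any(sides)) per_chrom[[nm]] <- sides
  }
  if (length(per_chrom) != 1L) return(NULL)  # nowhere, or several chromosomes
  sides <- per_chrom[[1L]]
  side <- if (all(sides)) "spanning" else if (sides[["left"]]) "left_of_gap"
          else "right_of_gap"
  list(chrom = names(per_chrom), side = side)
}

# per-position identity of two equal-length strings; alignment-based
# fallback when lengths differ
seq_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    mean(av == bv)
  } else {
    Biostrings::pid(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")) / 100
  }
}

#' Higher-order repeat period of a monomer array
#'
#' For each candidate period p in 1..floor(n/3), scores the mean identity
#' between monomer i and monomer i+p across the array. The dominant period
#' is the argmax, accepted only when it beats the period-1 score by at least
#' `margin` identity fraction; otherwise the array is called a pure tandem
#' (period 1). A period-1 call is flagged confident only when adjacent
#' copies really are near-identical (`score(1) >= tandem_identity`), so a
#' structureless array of divergent monomers - e.g. a randomized monomer
#' order - comes back as period 1 with `confident = FALSE`. Arrays shorter
#' than 6 monomers are undefined.
#'
#' @param monomer_seqs Character vector of the monomer sequences in array
#'   order (as extracted by [find_monomers()], strand-normalized).
#' @param margin Required identity advantage over period 1 (default 0.02).
#' @param tandem_identity Adjacent-copy identity required for a confident
#'   period-1 (pure tandem) call (default 0.95).
#' @return list `period`, `scores` (named by p), `confident` (logical),
#'   `defined` (FALSE when < 6 monomers).
#' @export
hor_period <- function(monomer_seqs, margin = 0.02, tandem_identity = 0.95) {
  n <- length(monomer_seqs)
  if (n < 6L) return(list(period = NA_integer_, scores = numeric(0),
                          confident = FALSE, defined = FALSE))
  monomer_seqs <- toupper(monomer_seqs)
  pmax_ <- floor(n / 3)
  scores <- vapply(seq_len(pmax_), function(p) {
    mean(vapply(seq_len(n - p), function(i)
      seq_identity(monomer_seqs[i], monomer_seqs[i + p]), numeric(1)))
  }, numeric(1))
  names(scores) <- seq_len(pmax_)
  best <- which.max(scores)
  if (best > 1L && scores[best] >= scores[1L] + margin)
    list(period = as.integer(best), scores = scores, confident = TRUE,
         defined = TRUE)
  else
    list(period = 1L, scores = scores,
         confident = scores[[1L]] >= tandem_identity,
         defined = TRUE)
}

#' Extract strand-normalized monomer sequences from find_monomers hits
#'
#' @param contig_seq The contig sequence.
#' @param hits The `hits` data.frame from [find_monomers()].
#' @return Character vector of monomer sequences in array order, minus-
#'   strand hits reverse-complemented.
#' @export
monomer_sequences <- function(contig_seq, hits) {
  contig_seq <- toupper(as.character(contig_seq))
  vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(contig_seq, hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
}

#' Self-identity matrix of a monomer array
#'
#' Pairwise identity between all monomers, for dotplot-style rendering.
#'
#' @param monomer_seqs Character vector of monomer sequences.
#' @return Numeric matrix of identities in [0,1].
#' @export
monomer_identity_matrix <- function(monomer_seqs) {
  n <- length(monomer_seqs)
  m <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- seq_identity(monomer_seqs[i], monomer_seqs[j])
  }
  m
}
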