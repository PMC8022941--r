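# Optical-map support of scaffolded contigs and adjudication of candidate
# inversions. Optical alignments are consumed as coordinates, either from a
# simplified TSV (optical_contig, chrom, start, end, collinear) or from an
# XMAP file via a thin converter (XMAP is 1-based closed; converted here).

#' Read optical alignments from a simplified TSV
#'
#' Columns: `optical_contig`, `chrom`, `start`, `end` (0-based half-open),
#' `collinear` (TRUE/FALSE).
#'
#' @param path TSV path.
#' @return data.frame of optical alignments.
#' @export
read_optical_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  fail_if(!all(c("optical_contig", "chrom", "start", "end", "collinear") %in%
                 names(x)), "missing optical alignment columns")
  fail_if(any(x$end <= x$start), "optical alignment with end <= start")
  x$collinear <- as.logical(x$collinear)
  x
}

#' Read optical alignments from XMAP
#'
#' Parses the coordinate columns of an XMAP file (header lines start with
#' `#`): XmapEntryID, QryContigID, RefContigID, QryStartPos, QryEndPos,
#' RefStartPos, RefEndPos, Orientation, Confidence, HitEnum... The alignment
#' cigar is ignored. Reference positions are 1-based; converted to 0-based
#' half-open. `ref_names` maps RefContigID to chromosome names. Collinearity
#' is approximated as a single monotonic alignment per row (XMAP rows are
#' monotonic by construction), so `collinear = TRUE`.
#'
#' @param path XMAP path.
#' @param ref_names Optional named character vector: RefContigID -> chrom.
#' @return data.frame as in [read_optical_tsv()].
#' @export
read_xmap <- function(path, ref_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(optical_contig = character(), chrom = character(),
                      start = numeric(), end = numeric(), collinear = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qry <- vapply(f, `[[`, character(1), 2L)
  ref <- vapply(f, `[[`, character(1), 3L)
  rs <- as.numeric(vapply(f, `[[`, character(1), 6L))
  re <- as.numeric(vapply(f, `[[`, character(1), 7L))
  chrom <- if (is.null(ref_names)) ref else unname(ref_names[ref])
  data.frame(optical_contig = paste0("opt", qry), chrom = chrom,
             start = pmin(rs, re) - 1, end = pmax(rs, re),
             collinear = TRUE, stringsAsFactors = FALSE)
}

#' Optical support of a contig interval
#'
#' The support fraction is the share of the contig's bases covered by at
#' least one optical alignment on its chromosome; the contig is supported
#' when that fraction is at least 0.5 (inclusive).
#'
#' @param chrom,start,end Contig interval within its scaffold (0-based
#'   half-open).
#' @param optical Optical alignment data.frame.
#' @param min_frac Support threshold (default 0.5).
#' @return list `supported` (logical), `fraction` (covered share).
#' @export
contig_support <- function(chrom, start, end, optical, min_frac = 0.5) {
  fail_if(end <= start, "empty contig interval")
  o <- optical[optical$chrom == chrom & optical$end > start & optical$start < end,
               , drop = FALSE]
  covered <- 0
  if (nrow(o)) {
    ir <- IRanges::reduce(IRanges::IRanges(pmax(o$start, start) + 1L,
                                           pmin(o$end, end)))
    covered <- sum(IRanges::width(ir))
  }
  frac <- covered / (end - start)
  list(supported = frac >= min_frac, fraction = frac)
}

#' Prune unsupported contigs from a scaffold
#'
#' Excises contigs not supported by the optical map, leaving a single spacer
#' gap (default 100 N) at each excision; retained contig sequence is never
#' altered. Removed contigs are returned as unplaced records.
#'
#' @param scaffold_seq Scaffold sequence (character or DNAString).
#' @param contig_table data.frame `name`, `start`, `end` tiling the scaffold
#'   (0-based half-open, sorted, gaps between contigs allowed as N-runs).
#' @param support Logical vector, one element per contig row.
#' @param spacer_len N-run inserted at each excision (default 100).
#' @return list `sequence` (pruned scaffold, character), `removed`
#'   (data.frame of excised contigs with their sequence).
#' @export
prune_unsupported <- function(scaffold_seq, contig_table, support,
                              spacer_len = 100L) {
  scaffold_seq <- as.character(scaffold_seq)
  fail_if(length(support) != nrow(contig_table),
          "support calls do not match contig table")
  fail_if(!any(support), "pruning would remove every contig in the scaffold")
  o <- order(contig_table$start)
  contig_table <- contig_table[o, , drop = FALSE]; support <- support[o]
  pieces <- character(0)
  removed <- list()
  spacer <- strrep("N", spacer_len)
  pending_spacer <- FALSE
  for (i in seq_len(nrow(contig_table))) {
    seq_i <- substr(scaffold_seq, contig_table$start[i] + 1L, contig_table$end[i])
    if (support[i]) {
      if (length(pieces)) {
        if (pending_spacer) {
          pieces <- c(pieces, spacer)
        } else {
          # keep the original inter-contig material (N run) before this contig
          pieces <- c(pieces, substr(scaffold_seq, contig_table$end[i - 1L] + 1L,
                                     contig_table$start[i]))
        }
      }
      pieces <- c(pieces, seq_i)
      pending_spacer <- FALSE
    } else {
      removed[[length(removed) + 1L]] <- data.frame(
        name = contig_table$name[i], start = contig_table$start[i],
        end = contig_table$end[i], sequence = seq_i, stringsAsFactors = FALSE)
      pending_spacer <- TRUE
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed)
  else data.frame(name = character(), start = numeric(), end = numeric(),
                  sequence = character(), stringsAsFactors = FALSE)
  list(sequence = paste(pieces, collapse = ""), removed = removed)
}

#' Adjudicate a candidate inversion against optical alignments
#'
#' An inversion call is supported only when its whole interval, padded by
#' `margin`, lies strictly inside a single collinear optical alignment; a
#' breakpoint at an optical contig edge, or absence of any overlapping
#' optical contig, leaves it unsupported.
#'
#' @param chrom,start,end Inversion interval (0-based half-open).
#' @param optical Optical alignment data.frame.
#' @param margin Padding in bp (default 10000).
#' @return `"supported"` or `"unsupported"`.
#' @export
adjudicate_inversion <- function(chrom, start, end, optical, margin = 10000) {
  o <- optical[optical$chrom == chrom & optical$collinear, , drop = FALSE]
  inside <- o$start < start - margin & o$end > end + margin
  if (any(inside)) "supported" else "unsupported"
}
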