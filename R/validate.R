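# Validation of closed gaps by two independent lines of evidence:
# (a) collinearity of the fill sequence against an independent assembly, and
# (b) barcoded linked-read molecule coverage across the filled locus.

#' Collinearity check of closed-gap fills against an independent assembly
#'
#' Each fill sequence is aligned (externally) to an independent assembly;
#' this routine filters those alignments with [filter_collinear()] and labels
#' every fill `concordant_chrom` when its best-aligned target chromosome
#' matches the homolog of the chromosome the gap sits on, `discordant_chrom`
#' when it aligns best elsewhere, or `unaligned` when no alignment survives
#' the filter.
#'
#' @param fills data.frame with columns `fill_id` and `chrom` (the
#'   chromosome carrying the closed gap).
#' @param blocks Alignment blocks of the fill sequences (query = `fill_id`)
#'   against the independent assembly.
#' @param homolog Named character vector mapping reference chromosome names
#'   to their homologs in the independent assembly (identity map by default).
#' @param min_identity,min_len Filter thresholds (defaults 0.98, 4000).
#' @return list `calls` (per-fill data.frame with `verdict` and best
#'   `target`), `fraction_aligned`, `fraction_discordant` (of aligned).
#' @export
collinearity_check <- function(fills, blocks, homolog = NULL,
                               min_identity = 0.98, min_len = 4000) {
  blocks <- filter_collinear(blocks, min_identity, min_len)
  verdict <- character(nrow(fills)); target <- rep(NA_character_, nrow(fills))
  for (i in seq_len(nrow(fills))) {
    b <- blocks[blocks$query == fills$fill_id[i], , drop = FALSE]
    if (nrow(b) == 0L) { verdict[i] <- "unaligned"; next }
    best <- b[which.max(b$matches), ]
    target[i] <- best$target
    expected <- if (is.null(homolog)) fills$chrom[i] else
      unname(homolog[fills$chrom[i]])
    verdict[i] <- if (identical(best$target, expected)) "concordant_chrom"
                  else "discordant_chrom"
  }
  aligned <- verdict != "unaligned"
  list(calls = cbind(fills, data.frame(verdict = verdict, target = target,
                                       stringsAsFactors = FALSE)),
       fraction_aligned = mean(aligned),
       fraction_discordant = if (any(aligned))
         mean(verdict[aligned] == "discordant_chrom") else NA_real_)
}

#' Reconstruct linked-read molecules from barcoded read alignments
#'
#' Reads sharing a barcode on one chromosome are clustered by single
#' linkage: a new molecule starts whenever the next read begins more than
#' `max_gap_within_molecule` bp after the end of the previous one. Reads
#' without a barcode are skipped (counted).
#'
#' @param reads data.frame with columns `read`, `barcode`, `chrom`, `start`,
#'   `end` (0-based half-open alignment intervals).
#' @param max_gap_within_molecule Split distance in bp (default 50000,
#'   matching a >= 50 kb molecule size selection).
#' @return list `molecules` (data.frame `molecule`, `barcode`, `chrom`,
#'   `span_start`, `span_end`, `n_reads`), `reads` (input reads annotated
#'   with their `molecule` id), `n_skipped` (barcode-less reads).
#' @export
group_molecules <- function(reads, max_gap_within_molecule = 50000) {
  miss <- is.na(reads$barcode) | !nzchar(reads$barcode)
  n_skipped <- sum(miss)
  r <- reads[!miss, , drop = FALSE]
  if (nrow(r) == 0L)
    return(list(molecules = data.frame(molecule = character(),
                                       barcode = character(), chrom = character(),
                                       span_start = numeric(), span_end = numeric(),
                                       n_reads = integer()),
                reads = cbind(r, molecule = character(0)),
                n_skipped = n_skipped))
  r <- r[order(r$barcode, r$chrom, r$start), , drop = FALSE]
  key <- paste(r$barcode, r$chrom, sep = "\r")
  new_grp <- c(TRUE, key[-1] != key[-nrow(r)] |
                 r$start[-1] - cummax_by(r$end, key)[-nrow(r)] > max_gap_within_molecule)
  grp <- cumsum(new_grp)
  r$molecule <- sprintf("mol%05d", grp)
  mol <- do.call(rbind, lapply(split(seq_len(nrow(r)), grp), function(idx) {
    data.frame(molecule = r$molecule[idx[1]], barcode = r$barcode[idx[1]],
               chrom = r$chrom[idx[1]], span_start = min(r$start[idx]),
               span_end = max(r$end[idx]), n_reads = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(mol) <- NULL
  list(molecules = mol, reads = r, n_skipped = n_skipped)
}

# running max of x within consecutive identical keys
cummax_by <- function(x, key) {
  out <- x
  for (i in seq_along(x)[-1]) {
    if (key[i] == key[i - 1]) out[i] <- max(out[i - 1], x[i])
  }
  out
}

#' Classify linked-read support of one closed gap
#'
#' A closed gap is `supported` when (a) every base of the fill interval
#' padded by `flank` has read depth at least `depth_threshold`, and (b) at
#' least one molecule has reads aligned on both flanks of the fill (so a
#' stray mis-mapped read inside the fill cannot rescue a bad closure).
#'
#' @param chrom,fill_start,fill_end Fill interval in new-assembly
#'   coordinates (from [ledger_fill_intervals()]).
#' @param grouped Output of [group_molecules()] (reads must be aligned to
#'   the new assembly).
#' @param depth_threshold Minimum depth (default 1).
#' @param flank Padding in bp (default 100).
#' @return list `verdict` ("supported"/"unsupported"), `min_depth_in_fill`,
#'   `spanning_molecules`.
#' @export
classify_gap_support <- function(chrom, fill_start, fill_end, grouped,
                                 depth_threshold = 1L, flank = 100L) {
  fail_if(fill_end - fill_start < 1, "fill interval shorter than 1 bp")
  r <- grouped$reads[grouped$reads$chrom == chrom, , drop = FALSE]
  lo <- fill_start - flank; hi <- fill_end + flank
  depth_min <- 0L
  if (nrow(r)) {
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    cov <- IRanges::coverage(ir, width = as.integer(max(hi, max(r$end)) + 1L))
    depth_min <- min(as.integer(cov[max(1L, lo + 1L):hi]))
    if (lo < 0) depth_min <- 0L
  }
  left_ok <- r$start < fill_start & r$end > lo
  right_ok <- r$end > fill_end & r$start < hi
  span <- intersect(unique(r$molecule[left_ok]), unique(r$molecule[right_ok]))
  supported <- depth_min >= depth_threshold && length(span) >= 1L
  list(verdict = if (supported) "supported" else "unsupported",
       min_depth_in_fill = depth_min, spanning_molecules = length(span))
}

#' Validate all closed gaps with linked reads
#'
#' @param ledger A `patch_ledger` of applied fills.
#' @param grouped Output of [group_molecules()].
#' @inheritParams classify_gap_support
#' @return data.frame with one row per gap-fill edit: fill interval,
#'   `verdict`, `min_depth_in_fill`, `spanning_molecules`; plus attribute
#'   `fraction_supported`.
#' @export
validate_gaps_linked <- function(ledger, grouped, depth_threshold = 1L,
                                 flank = 100L) {
  iv <- ledger_fill_intervals(ledger)
  iv <- iv[iv$kind == "gap_fill" & iv$new_end > iv$new_start, , drop = FALSE]
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    cl <- classify_gap_support(iv$chrom[i], iv$new_start[i], iv$new_end[i],
                               grouped, depth_threshold, flank)
    data.frame(chrom = iv$chrom[i], fill_start = iv$new_start[i],
               fill_end = iv$new_end[i], verdict = cl$verdict,
               min_depth_in_fill = cl$min_depth_in_fill,
               spanning_molecules = cl$spanning_molecules,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(chrom = character(), fill_start = numeric(),
                  fill_end = numeric(), verdict = character(),
                  min_depth_in_fill = integer(), spanning_molecules = integer())
  attr(out, "fraction_supported") <- if (nrow(out))
    mean(out$verdict == "supported") else NA_real_
  out
}

#' Alignment rate and mean depth of a read set
#'
#' @param reads data.frame of aligned reads (`chrom`, `start`, `end`).
#' @param n_total Total number of input reads (aligned + unaligned).
#' @param asm The `assembly` the reads were aligned to.
#' @return list `alignment_rate` (fraction), `mean_depth` (aligned bases /
#'   non-N assembly size).
#' @export
coverage_stats <- function(reads, n_total, asm) {
  if (n_total == 0L) return(list(alignment_rate = 0, mean_depth = 0))
  size <- contiguity_metrics(asm)$assembly_size_no_N
  list(alignment_rate = nrow(reads) / n_total,
       mean_depth = if (size > 0) sum(reads$end - reads$start) / size else 0)
}
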