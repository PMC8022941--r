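# Assembly container, gap detection and contiguity metrics.
#
# An assembly is a set of named nucleotide sequences partitioned into
# chromosome scaffolds and unplaced contigs. Chromosome scaffolds may contain
# runs of N marking unassembled sequence between contigs ("gaps"). All
# coordinates in this package are 0-based half-open; 1-based closed
# conventions appear only at serialization boundaries (BED stays 0-based,
# XMAP/AGP-like tables are converted at the parser edge).

#' Construct an assembly from sequences
#'
#' @param seqs A named `Biostrings::DNAStringSet`, or a named character vector
#'   of nucleotide strings (case-insensitive; non-ACGTN symbols are replaced
#'   by N with a warning).
#' @param unplaced_pattern Regular expression applied to sequence names to
#'   classify a record as `"unplaced"` rather than `"chromosome"`. The default
#'   matches the common naming of unplaced material (`chrUn*`, `scaffold*`).
#' @param category Optional explicit character vector (`"chromosome"` /
#'   `"unplaced"`, recycled or full length) overriding the name rule.
#'
#' @return An object of class `assembly`: a list with elements `seqs`
#'   (`DNAStringSet`) and `category` (named character vector).
#' @examples
#' asm <- assembly(c(chrI = "ACGTNNNNACGT", chrUn_1 = "ACGT"))
#' asm$category
#' @export
assembly <- function(seqs, unplaced_pattern = "^(chrUn|scaffold)", category = NULL) {
  if (is.character(seqs)) {
    fail_if(is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))),
            "all sequences must be named")
    seqs <- vapply(seq_along(seqs), function(i) sanitize_seq(seqs[[i]], names(seqs)[i]),
                   character(1), USE.NAMES = FALSE) |>
      stats::setNames(names(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  fail_if(!methods::is(seqs, "DNAStringSet"), "seqs must be a DNAStringSet or named character")
  fail_if(anyDuplicated(names(seqs)) > 0, "duplicate sequence names in assembly")
  fail_if(any(Biostrings::width(seqs) < 1L), "zero-length sequence in assembly")
  if (is.null(category)) {
    category <- ifelse(grepl(unplaced_pattern, names(seqs)), "unplaced", "chromosome")
  } else {
    category <- rep_len(category, length(seqs))
    fail_if(!all(category %in% c("chromosome", "unplaced")),
            "category must be 'chromosome' or 'unplaced'")
  }
  names(category) <- names(seqs)
  structure(list(seqs = seqs, category = category), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  n_chr <- sum(x$category == "chromosome")
  cat(sprintf("<assembly> %d sequence(s): %d chromosome, %d unplaced; %s bp total\n",
              length(x$seqs), n_chr, length(x$seqs) - n_chr,
              format(sum(as.numeric(Biostrings::width(x$seqs))), big.mark = ",")))
  invisible(x)
}

#' Read an assembly from FASTA
#'
#' @param path FASTA file.
#' @inheritParams assembly
#' @return An `assembly`.
#' @export
read_assembly <- function(path, unplaced_pattern = "^(chrUn|scaffold)") {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly(seqs, unplaced_pattern = unplaced_pattern)
}

#' Write an assembly to FASTA
#'
#' @param asm An `assembly`.
#' @param path Output file.
#' @param width Line wrap width (default 60).
#' @export
write_assembly <- function(asm, path, width = 60L) {
  Biostrings::writeXStringSet(asm$seqs, path, width = width)
  invisible(path)
}

# widths as a plain numeric vector, named
asm_widths <- function(asm) stats::setNames(as.numeric(Biostrings::width(asm$seqs)),
                                            names(asm$seqs))

#' Find assembly gaps (maximal N runs)
#'
#' Scans every chromosome-category sequence for maximal runs of `N` of length
#' at least `min_run`. Unplaced sequences are never scanned: a gap is defined
#' as missing sequence *within* a chromosome scaffold. Runs touching the
#' scaffold ends count as gaps too.
#'
#' @param asm An `assembly`.
#' @param min_run Minimum N-run length to report (default 1).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `status` (all `"open"`), sorted by (chrom, start).
#' @examples
#' find_gaps(assembly(c(chrI = "ACGTNNNNACGT")))
#' @export
find_gaps <- function(asm, min_run = 1L) {
  fail_if(min_run < 1L, "min_run must be >= 1")
  keep <- names(asm$seqs)[asm$category == "chromosome"]
  out <- lapply(keep, function(nm) {
    ir <- nrun_ranges(asm$seqs[[nm]])
    ir <- ir[IRanges::width(ir) >= min_run]
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = nm,
               start = IRanges::start(ir) - 1L,   # IRanges is 1-based closed
               end   = IRanges::end(ir),
               length = IRanges::width(ir),
               status = "open",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), status = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE] |> `rownames<-`(NULL)
}

# maximal N runs of a DNAString as an IRanges (1-based).
# fixed = TRUE so pattern N matches only literal N in the subject.
nrun_ranges <- function(seq) {
  hits <- Biostrings::matchPattern("N", seq, fixed = TRUE)
  IRanges::reduce(methods::as(hits, "IRanges"))
}

#' Contiguity metrics of an assembly
#'
#' Contigs are the gap-free segments of chromosome scaffolds (each maximal
#' N-run splits its scaffold). N50 is the length of the shortest contig in the
#' smallest set of longest contigs whose summed length reaches at least 50% of
#' the total contig length; L50 is the size of that set. N90/L90 are the 90%
#' analogues.
#'
#' @param asm An `assembly`.
#' @param gaps Optional precomputed gap table from [find_gaps()]; recomputed
#'   when missing.
#' @return A list with `n_gaps`, `contig_N50`, `contig_N90`, `L50`, `L90`,
#'   `assembly_size_no_N` (all sequences, N excluded) and
#'   `assembly_size_no_N_no_unplaced` (chromosomes only).
#' @export
contiguity_metrics <- function(asm, gaps = NULL) {
  if (is.null(gaps)) gaps <- find_gaps(asm)
  w <- asm_widths(asm)
  chroms <- names(asm$seqs)[asm$category == "chromosome"]
  lens <- unlist(lapply(chroms, function(nm) {
    g <- gaps[gaps$chrom == nm, , drop = FALSE]
    contig_segments(w[[nm]], g$start, g$end)
  }), use.names = FALSE)
  if (is.null(lens)) lens <- numeric(0)
  nl <- n50_l50(lens, 0.5)
  nl9 <- n50_l50(lens, 0.9)
  n_count <- sum(vapply(names(asm$seqs), function(nm)
    Biostrings::countPattern("N", asm$seqs[[nm]]), numeric(1)))
  n_count_chr <- sum(vapply(chroms, function(nm)
    Biostrings::countPattern("N", asm$seqs[[nm]]), numeric(1)))
  list(n_gaps = nrow(gaps),
       contig_N50 = nl$n, contig_N90 = nl9$n,
       L50 = nl$l, L90 = nl9$l,
       assembly_size_no_N = sum(w) - n_count,
       assembly_size_no_N_no_unplaced = sum(w[chroms]) - n_count_chr)
}

# lengths of gap-free segments of one scaffold given gap coords (0-based half-open)
contig_segments <- function(chrom_len, gap_start, gap_end) {
  if (length(gap_start) == 0L) return(chrom_len)
  o <- order(gap_start)
  gap_start <- gap_start[o]; gap_end <- gap_end[o]
  bounds_s <- c(0, gap_end)
  bounds_e <- c(gap_start, chrom_len)
  lens <- bounds_e - bounds_s
  lens[lens > 0]
}

n50_l50 <- function(lens, frac) {
  if (length(lens) == 0L) return(list(n = 0, l = 0L))
  lens <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= frac * sum(lens))[1]
  list(n = lens[i], l = i)
}

#' Fold change between two metric values
#'
#' @param metric_new,metric_old Values on the same scale; `metric_old` must be
#'   positive.
#' @return `metric_new / metric_old` rounded to 2 decimals.
#' @examples
#' fold_change(510.82, 91.68)  # 5.57
#' @export
fold_change <- function(metric_new, metric_old) {
  fail_if(metric_old <= 0, "metric_old must be > 0")
  round(metric_new / metric_old, 2)
}
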