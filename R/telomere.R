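# Telomere discovery in raw long reads. Telomeric reads are detected by
# counting the conserved metazoan hexamer TTAGGG (or its reverse complement
# CCCTAA), assigned to a chromosome end when enough uniquely aligning
# sequence anchors them there, and their unaligned telomeric overhang is
# merged onto the chromosome terminus as an end-extension ledger edit.

TELOMERE_FWD <- "TTAGGG"
TELOMERE_REV <- "CCCTAA"

#' Count non-overlapping motif occurrences
#'
#' Case-insensitive, exact, left-to-right non-overlapping scan (no
#' degenerate-base matching).
#'
#' @param sequence Nucleotide string (character scalar or DNAString).
#' @param motif Non-empty motif string.
#' @return Integer count.
#' @examples
#' count_motif(strrep("TTAGGG", 60), "TTAGGG")
#' @export
count_motif <- function(sequence, motif) {
  fail_if(!nzchar(motif), "motif must be non-empty")
  sequence <- toupper(as.character(sequence))
  length(gregexpr(toupper(motif), sequence, fixed = TRUE)[[1]] |>
           (\(m) m[m > 0])())
}

#' Select telomeric reads by motif count
#'
#' A read is a telomere candidate when it contains strictly more than
#' `threshold` occurrences of the forward motif TTAGGG or of the reverse
#' motif CCCTAA.
#'
#' @param reads Named character vector or `DNAStringSet` of raw reads.
#' @param threshold Occurrence threshold (default 50; strict inequality).
#' @return data.frame `read`, `motif_count_fwd`, `motif_count_rev` of the
#'   retained candidates.
#' @export
select_telomeric_reads <- function(reads, threshold = 50L) {
  fail_if(threshold < 1L, "threshold must be >= 1")
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  fwd <- vapply(reads, count_motif, integer(1), motif = TELOMERE_FWD,
                USE.NAMES = FALSE)
  rev <- vapply(reads, count_motif, integer(1), motif = TELOMERE_REV,
                USE.NAMES = FALSE)
  keep <- fwd > threshold | rev > threshold
  data.frame(read = names(reads)[keep], motif_count_fwd = fwd[keep],
             motif_count_rev = rev[keep], stringsAsFactors = FALSE)
}

#' Assign a telomeric read to a chromosome end
#'
#' The read is assigned to the end of a chromosome when more than
#' `min_unique` bp of its sequence aligns uniquely (primary alignments,
#' coverage multiplicity 1) within `end_window` bp of that terminus. A read
#' anchoring at the ends of two different chromosomes, or at both ends of
#' one, is ambiguous and gets no assignment.
#'
#' @param blocks Primary alignment blocks of one read against the assembly.
#' @param chrom_lens Named numeric vector of chromosome lengths.
#' @param min_unique Minimum unique anchor span in bp (default 10000,
#'   strict).
#' @param end_window Window from each terminus in bp (default 50000).
#' @return list `chrom`, `side` ("left"/"right"), `unique_anchor_bp`; or
#'   NULL when unassigned.
#' @export
assign_telomere <- function(blocks, chrom_lens, min_unique = 10000,
                            end_window = 50000) {
  blocks <- blocks[blocks$is_primary, , drop = FALSE]
  if (nrow(blocks) == 0L) return(NULL)
  hits <- list()
  for (nm in intersect(unique(blocks$target), names(chrom_lens))) {
    len <- chrom_lens[[nm]]
    for (side in c("left", "right")) {
      reg <- if (side == "left") c(0, min(end_window, len))
             else c(max(0, len - end_window), len)
      span <- unique_anchor_span(blocks, nm, reg[1], reg[2])
      if (span > min_unique)
        hits[[length(hits) + 1L]] <- list(chrom = nm, side = side,
                                          unique_anchor_bp = span)
    }
  }
  if (length(hits) != 1L) return(NULL)  # none, or ambiguous
  hits[[1L]]
}

#' Merge a telomeric read's overhang onto a chromosome end
#'
#' The aligned portion of the read overlaps existing chromosome sequence and
#' is never duplicated; only the unaligned telomeric overhang beyond the
#' terminus is appended (right end) or prepended (left end), reverse-
#' complemented when the anchoring alignment is on the minus strand.
#' Existing chromosome bases are never modified.
#'
#' @param assignment Output of [assign_telomere()].
#' @param blocks The read's primary blocks on the assigned chromosome.
#' @param read_seq The read sequence.
#' @param chrom_len Length of the assigned chromosome.
#' @return A one-edit `patch_ledger` (kind `end_extension`), or NULL when
#'   there is no overhang.
#' @export
merge_telomere <- function(assignment, blocks, read_seq, chrom_len) {
  if (is.null(assignment)) return(NULL)
  read_seq <- toupper(as.character(read_seq))
  b <- blocks[blocks$is_primary & blocks$target == assignment$chrom, , drop = FALSE]
  if (nrow(b) == 0L) return(NULL)
  b <- b[which.max(b$matches), ]
  rlen <- nchar(read_seq)
  if (assignment$side == "right") {
    # overhang = read sequence beyond the terminus-proximal end of the anchor
    overhang <- if (b$strand == "+") substr(read_seq, b$q_end + 1L, rlen)
                else if (b$q_start >= 1L) revcomp_chr(substr(read_seq, 1L, b$q_start))
                else ""
    if (!nzchar(overhang)) return(NULL)
    patch_ledger(assignment$chrom, chrom_len, chrom_len, overhang,
                 fill_source = "telomere_read", kind = "end_extension")
  } else {
    overhang <- if (b$strand == "+") substr(read_seq, 1L, b$q_start)
                else if (b$q_end < rlen) revcomp_chr(substr(read_seq, b$q_end + 1L, rlen))
                else ""
    if (!nzchar(overhang)) return(NULL)
    patch_ledger(assignment$chrom, 0L, 0L, overhang,
                 fill_source = "telomere_read", kind = "end_extension")
  }
}

#' Telomere discovery pipeline over a read set
#'
#' Runs [select_telomeric_reads()], [assign_telomere()] and
#' [merge_telomere()] over all reads and combines the resulting
#' end-extension edits (at most one per chromosome end: the longest overhang
#' wins).
#'
#' @param reads Named character/`DNAStringSet` of raw reads.
#' @param blocks Primary alignments of the reads to the assembly.
#' @param asm The `assembly`.
#' @param threshold Motif-count threshold (default 50).
#' @param min_unique,end_window See [assign_telomere()].
#' @return list `candidates` (selection table with assignment columns),
#'   `ledger` (end-extension `patch_ledger`).
#' @export
find_telomeres <- function(reads, blocks, asm, threshold = 50L,
                           min_unique = 10000, end_window = 50000) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  cand <- select_telomeric_reads(reads, threshold)
  cand$chrom <- NA_character_; cand$side <- NA_character_
  cand$unique_anchor_bp <- 0
  chrom_lens <- asm_widths(asm)[asm$category == "chromosome"]
  edits <- list()
  for (i in seq_len(nrow(cand))) {
    b <- blocks[blocks$query == cand$read[i], , drop = FALSE]
    asg <- assign_telomere(b, chrom_lens, min_unique, end_window)
    if (is.null(asg)) next
    cand$chrom[i] <- asg$chrom; cand$side[i] <- asg$side
    cand$unique_anchor_bp[i] <- asg$unique_anchor_bp
    led <- merge_telomere(asg, b, reads[[cand$read[i]]], chrom_lens[[asg$chrom]])
    if (!is.null(led)) {
      key <- paste(asg$chrom, asg$side)
      if (is.null(edits[[key]]) || led$new_len[1] > edits[[key]]$new_len[1])
        edits[[key]] <- led
    }
  }
  ledger <- if (length(edits)) do.call(bind_ledgers, unname(edits))
            else patch_ledger()
  list(candidates = cand, ledger = ledger)
}
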