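# Gap closing with donor contigs.
#
# A gap is closed by a pair of anchor alignments from one donor contig, one
# ending near the gap's left edge and one starting near its right edge, on a
# consistent strand. The donor sequence between the two anchor images of the
# gap boundaries becomes the fill. A length-deviation tolerance `a` controls
# how far the fill length may differ from the recorded gap length (gap sizes
# in draft assemblies are estimates). Donors whose anchors imply a negative
# fill length would ligate the two gap ends and delete flanking sequence;
# these mis-ligation candidates are excluded by the shrinkage guard. Gaps
# with a single-flank anchor are partially filled from that side.

closure_row <- function(gap, outcome, fill_source = NA_character_,
                        strand = NA_character_, fill_len = NA_real_,
                        deviation = NA_real_, added_bases = 0,
                        replacement = NA_character_, edit_start = NA_real_,
                        edit_end = NA_real_) {
  data.frame(chrom = gap$chrom, gap_start = gap$start, gap_end = gap$end,
             gap_len = gap$end - gap$start, outcome = outcome,
             fill_source = fill_source, strand = strand, fill_len = fill_len,
             deviation = deviation, added_bases = added_bases,
             replacement = replacement, edit_start = edit_start,
             edit_end = edit_end, stringsAsFactors = FALSE)
}

#' Find donor anchor alignments for one gap
#'
#' A left anchor is a block on the gap's chromosome whose target interval
#' ends within `flank` bp upstream of the gap start (without crossing into
#' the gap); a right anchor starts within `flank` bp downstream of the gap
#' end. Anchors are expected to come from alignments that already passed
#' [filter_collinear()].
#'
#' @param gap One row of a [find_gaps()] table (list-like with `chrom`,
#'   `start`, `end`).
#' @param blocks Alignment-block data.frame (donor -> reference).
#' @param flank Anchoring window in bp (default 1000).
#' @return list with data.frames `left` and `right`.
#' @export
anchor_contigs <- function(gap, blocks, flank = 1000) {
  b <- blocks[blocks$target == gap$chrom & blocks$is_primary, , drop = FALSE]
  left <- b[b$t_end <= gap$start & b$t_end >= gap$start - flank, , drop = FALSE]
  right <- b[b$t_start >= gap$end & b$t_start <= gap$end + flank, , drop = FALSE]
  list(left = left, right = right)
}

# donor coordinate corresponding to a reference position, extrapolated
# collinearly from an anchor block. side: which anchor edge we extend from.
donor_pos_at <- function(block, ref_pos) {
  if (block$strand == "+") {
    if (ref_pos >= block$t_end) block$q_end + (ref_pos - block$t_end)
    else block$q_start + (ref_pos - block$t_start)
  } else {
    # minus strand: increasing target = decreasing donor coordinate
    if (ref_pos >= block$t_end) block$q_start - (ref_pos - block$t_end)
    else block$q_end - (ref_pos - block$t_start)
  }
}

#' Close a gap from a spanning anchor pair
#'
#' The two anchors must come from the same donor contig on the same strand.
#' The fill is the donor sequence between the donor images of the two gap
#' boundaries (reverse-complemented for minus-strand donors). Outcomes:
#' `closed` when the relative length deviation |fill - gap| / max(gap, 1) is
#' at most `a`; `rejected_deviation` otherwise; `shrinkage_candidate` when
#' the implied fill length is negative (the donor would ligate the gap ends
#' and delete flank - resolved by [shrinkage_guard()]); `rejected_order` when
#' the anchors are ordered inconsistently on the donor (non-linear homology).
#'
#' @param left,right One-row anchor blocks from [anchor_contigs()].
#' @param donor_seq Donor contig sequence (character or DNAString).
#' @param gap Gap record (list-like with `chrom`, `start`, `end`).
#' @param a Allowed deviation ratio (default 1.0).
#' @return One-row closure data.frame.
#' @export
close_gap <- function(left, right, donor_seq, gap, a = 1.0) {
  fail_if(left$query != right$query, "anchors from different donors")
  fail_if(left$strand != right$strand, "anchors on inconsistent strands")
  donor_seq <- as.character(donor_seq)
  strand <- left$strand
  out_of_order <- if (strand == "+") right$q_end <= left$q_start
                  else left$q_end <= right$q_start
  if (out_of_order)
    return(closure_row(gap, "rejected_order", left$query, strand))
  if (strand == "+") {
    fs <- donor_pos_at(left, gap$start)
    fe <- donor_pos_at(right, gap$end)
  } else {
    fs <- donor_pos_at(right, gap$end)    # donor-forward start
    fe <- donor_pos_at(left, gap$start)
  }
  fill_len <- fe - fs
  if (fill_len < 0)
    return(closure_row(gap, "shrinkage_candidate", left$query, strand,
                       fill_len = fill_len))
  fs <- max(0, fs); fe <- min(nchar(donor_seq), fe)
  fill <- substr(donor_seq, fs + 1L, fe)
  if (strand == "-" && nzchar(fill)) fill <- revcomp_chr(fill)
  gap_len <- gap$end - gap$start
  deviation <- abs(fill_len - gap_len) / max(gap_len, 1)
  if (deviation > a)
    return(closure_row(gap, "rejected_deviation", left$query, strand,
                       fill_len = fill_len, deviation = deviation))
  closure_row(gap, "closed", left$query, strand, fill_len = nchar(fill),
              deviation = deviation, added_bases = nchar(gsub("N", "", fill)),
              replacement = fill, edit_start = gap$start, edit_end = gap$end)
}

#' Partially fill a gap from a single-flank anchor
#'
#' Inserts the donor overhang beyond the anchored flank into the gap,
#' capped at min(overhang, gap length, `max_ext`). The rest of the gap
#' remains N, so partial fills never change scaffold length.
#'
#' @param anchor One-row anchor block.
#' @param side `"left"` or `"right"`: which gap flank the anchor abuts.
#' @param donor_seq Donor contig sequence.
#' @param gap Gap record.
#' @param max_ext Cap on inserted bases (default `Inf`).
#' @return One-row closure data.frame (`partial_left`, `partial_right`, or
#'   `unfilled` when the donor has no overhang).
#' @export
extend_gap <- function(anchor, side = c("left", "right"), donor_seq, gap,
                       max_ext = Inf) {
  side <- match.arg(side)
  donor_seq <- as.character(donor_seq)
  dlen <- nchar(donor_seq)
  gap_len <- gap$end - gap$start
  if (side == "left") {
    p <- donor_pos_at(anchor, gap$start)
    overhang <- if (anchor$strand == "+") dlen - p else p
  } else {
    p <- donor_pos_at(anchor, gap$end)
    overhang <- if (anchor$strand == "+") p else dlen - p
  }
  overhang <- max(0, min(overhang, dlen))
  cap <- floor(min(overhang, gap_len, max_ext))
  if (cap <= 0) return(closure_row(gap, "unfilled", anchor$query, anchor$strand))
  take <- function(s, e) substr(donor_seq, s + 1L, e)
  if (side == "left") {
    fill <- if (anchor$strand == "+") take(p, p + cap)
            else revcomp_chr(take(p - cap, p))
    es <- gap$start; ee <- gap$start + cap
  } else {
    fill <- if (anchor$strand == "+") take(p - cap, p)
            else revcomp_chr(take(p, p + cap))
    es <- gap$end - cap; ee <- gap$end
  }
  closure_row(gap, paste0("partial_", side), anchor$query, anchor$strand,
              fill_len = cap, added_bases = nchar(gsub("N", "", fill)),
              replacement = fill, edit_start = es, edit_end = ee)
}

#' Mis-ligation (shrinkage) guard
#'
#' Rejects any proposed fill whose application would reduce the chromosome
#' length below (old length - gap length), i.e. would delete flanking non-N
#' sequence by erroneously ligating the two gap ends. With fills restricted
#' to the gap interval this is exactly the negative-fill-length condition.
#'
#' @param closures Closure data.frame from [close_gap()]/[extend_gap()].
#' @return list `accepted` (closures to apply) and `rejected` (with outcome
#'   rewritten to `rejected_shrinkage`).
#' @export
shrinkage_guard <- function(closures) {
  if (nrow(closures) == 0L) return(list(accepted = closures, rejected = closures))
  # net length change of an edit is fill_len - (edit_end - edit_start);
  # shrinkage = chromosome shrinks by more than the gap length
  span <- ifelse(is.na(closures$edit_start), closures$gap_len,
                 closures$edit_end - closures$edit_start)
  delta <- ifelse(is.na(closures$fill_len), 0, closures$fill_len) - span
  bad <- closures$outcome == "shrinkage_candidate" | delta < -closures$gap_len
  rejected <- closures[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$outcome <- "rejected_shrinkage"
  list(accepted = closures[!bad, , drop = FALSE], rejected = rejected)
}

# pick the best spanning closure among competing donors:
# highest summed anchor identity, then longest summed anchor span, then NA (tie)
best_candidate <- function(cands, scores) {
  o <- order(-scores$identity, -scores$span)
  top <- o[1]
  tie <- scores$identity == scores$identity[top] & scores$span == scores$span[top]
  if (sum(tie) > 1L) return(NULL)  # unresolvable tie: reject and log
  top
}

#' Run the full gap-filling pass
#'
#' For every gap: filter donor alignments ([filter_collinear()], primary
#' only), find flank anchors, close with the best spanning donor pair or
#' partially fill from a single flank, apply the shrinkage guard, and emit a
#' patch ledger plus a per-gap closure report. One fill per gap; a single
#' pass. Deterministic given inputs and configuration.
#'
#' @param asm Reference `assembly` (old coordinates).
#' @param gaps Gap table from [find_gaps()].
#' @param donors Named `DNAStringSet` (or named character) of donor contigs.
#' @param blocks Donor->reference alignment blocks ([parse_paf()]).
#' @param a Deviation tolerance (default 1.0).
#' @param flank Anchor window bp (default 1000).
#' @param min_identity,min_len Collinearity-filter thresholds applied to the
#'   candidate anchor alignments (defaults 0.98 and 4000).
#' @param max_ext Cap on partial-fill length (default `Inf`).
#' @return list with `ledger` (a `patch_ledger`), `report` (per-gap closure
#'   data.frame) and `counts` (named vector over outcomes, plus
#'   `pct_closed`).
#' @export
run_gapfill <- function(asm, gaps, donors, blocks, a = 1.0, flank = 1000,
                        min_identity = 0.98, min_len = 4000, max_ext = Inf) {
  if (is.character(donors)) donors <- Biostrings::DNAStringSet(toupper(donors))
  blocks <- filter_collinear(blocks, min_identity, min_len)
  blocks <- blocks[blocks$is_primary, , drop = FALSE]
  rows <- vector("list", nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    gap <- gaps[i, ]
    anc <- anchor_contigs(gap, blocks, flank)
    cands <- list(); scores <- list()
    keys <- intersect(paste(anc$left$query, anc$left$strand),
                      paste(anc$right$query, anc$right$strand))
    for (key in keys) {
      l <- anc$left[paste(anc$left$query, anc$left$strand) == key, , drop = FALSE]
      r <- anc$right[paste(anc$right$query, anc$right$strand) == key, , drop = FALSE]
      l <- l[which.max(l$t_end), ]   # anchor closest to the gap edge
      r <- r[which.min(r$t_start), ]
      if (!l$query %in% names(donors)) next
      cl <- close_gap(l, r, donors[[l$query]], gap, a = a)
      cands[[length(cands) + 1L]] <- cl
      scores[[length(scores) + 1L]] <- data.frame(
        identity = l$identity + r$identity,
        span = (l$t_end - l$t_start) + (r$t_end - r$t_start))
    }
    row <- NULL
    if (length(cands)) {
      ok <- vapply(cands, function(x) x$outcome == "closed", logical(1))
      if (any(ok)) {
        sc <- do.call(rbind, scores[ok])
        pick <- best_candidate(cands[ok], sc)
        row <- if (is.null(pick)) NULL else cands[ok][[pick]]
        if (is.null(row)) {
          warning(sprintf("gap %s:%d-%d: tied spanning donors, rejected",
                          gap$chrom, gap$start, gap$end), call. = FALSE)
          row <- closure_row(gap, "unfilled")
        }
      } else {
        # no clean closure; surface the most informative failure
        pref <- c("shrinkage_candidate", "rejected_deviation", "rejected_order")
        oc <- vapply(cands, `[[`, character(1), "outcome")
        row <- cands[[which(oc == pref[pref %in% oc][1])[1]]]
      }
    }
    if (is.null(row)) {
      # single-flank partials
      part <- NULL
      if (nrow(anc$left) > 0) {
        l <- anc$left[which.max(anc$left$identity * (anc$left$q_end - anc$left$q_start)), ]
        if (l$query %in% names(donors))
          part <- extend_gap(l, "left", donors[[l$query]], gap, max_ext)
      }
      if ((is.null(part) || part$outcome == "unfilled") && nrow(anc$right) > 0) {
        r <- anc$right[which.max(anc$right$identity * (anc$right$q_end - anc$right$q_start)), ]
        if (r$query %in% names(donors)) {
          p2 <- extend_gap(r, "right", donors[[r$query]], gap, max_ext)
          if (is.null(part) || p2$outcome != "unfilled") part <- p2
        }
      }
      row <- if (is.null(part)) closure_row(gap, "unfilled") else part
    }
    rows[[i]] <- row
  }
  report <- do.call(rbind, rows)
  guard <- shrinkage_guard(report)
  report <- rbind(guard$accepted, guard$rejected)
  report <- report[order(report$chrom, report$gap_start), , drop = FALSE]
  rownames(report) <- NULL
  fills <- report[report$outcome %in% c("closed", "partial_left", "partial_right") &
                    !is.na(report$replacement), , drop = FALSE]
  # guard property: every replaced slice must be all N in the old assembly
  if (nrow(fills)) {
    for (k in seq_len(nrow(fills))) {
      slice <- substr(as.character(asm$seqs[[fills$chrom[k]]]),
                      fills$edit_start[k] + 1L, fills$edit_end[k])
      fail_if(grepl("[^N]", slice),
              "internal error: fill would overwrite non-N bases at %s:%d-%d",
              fills$chrom[k], fills$edit_start[k], fills$edit_end[k])
    }
  }
  ledger <- if (nrow(fills))
    patch_ledger(fills$chrom, fills$edit_start, fills$edit_end,
                 fills$replacement, fills$fill_source, "gap_fill")
  else patch_ledger()
  oc <- factor(report$outcome,
               levels = c("closed", "partial_left", "partial_right", "unfilled",
                          "rejected_deviation", "rejected_shrinkage",
                          "rejected_order"))
  counts <- table(oc)
  list(ledger = ledger, report = report,
       counts = c(as.list(counts),
                  pct_closed = round(100 * counts[["closed"]] / max(1, nrow(gaps)), 1)))
}
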