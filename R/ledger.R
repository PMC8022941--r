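# Patch ledger: the ordered record of edits (gap fills, end extensions)
# transforming one assembly version into the next. Each edit replaces an old
# interval [start, end) on a chromosome by a replacement sequence. End
# extensions are edits with an empty old interval at position 0 (prepend) or
# at the old chromosome length (append). The ledger is the single source of
# truth for the old->new coordinate liftover.

#' Construct a patch ledger
#'
#' @param chrom,start,end Old-assembly coordinates (0-based half-open) of the
#'   replaced interval; `start == end` denotes a pure insertion.
#' @param replacement Character vector of replacement sequences (may contain
#'   N for partial fills; may be "" for a pure deletion).
#' @param fill_source Identifier of the donor sequence providing the fill
#'   (NA allowed).
#' @param kind `"gap_fill"` or `"end_extension"`.
#' @return A data.frame of class `patch_ledger`, sorted by (chrom, start),
#'   with a `new_len` column (nchar of replacement).
#' @export
patch_ledger <- function(chrom = character(), start = integer(), end = integer(),
                         replacement = character(), fill_source = NA_character_,
                         kind = "gap_fill") {
  led <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    replacement = toupper(as.character(replacement)),
                    new_len = nchar(replacement),
                    fill_source = rep_len(as.character(fill_source), length(chrom)),
                    kind = rep_len(kind, length(chrom)),
                    stringsAsFactors = FALSE)
  fail_if(any(led$end < led$start), "edit with end < start")
  fail_if(!all(led$kind %in% c("gap_fill", "end_extension")),
          "kind must be gap_fill or end_extension")
  led <- led[order(led$chrom, led$start, led$end), , drop = FALSE]
  rownames(led) <- NULL
  # non-overlap within chromosome (abutting edits are fine)
  for (nm in unique(led$chrom)) {
    e <- led[led$chrom == nm, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop(sprintf("coordinate conflict: overlapping edits on %s", nm), call. = FALSE)
  }
  class(led) <- c("patch_ledger", "data.frame")
  led
}

#' Combine ledgers
#'
#' @param ... `patch_ledger` objects.
#' @return A single validated `patch_ledger`.
#' @export
bind_ledgers <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, logical(1))]
  if (length(parts) == 0L) return(patch_ledger())
  x <- do.call(rbind, lapply(parts, as.data.frame))
  patch_ledger(x$chrom, x$start, x$end, x$replacement, x$fill_source, x$kind)
}

#' Apply a patch ledger to an assembly
#'
#' Replaces each old interval with its fill. Untouched sequence is preserved
#' byte for byte; the new chromosome length equals the old length plus the
#' ledger's net length change. Edits must lie within the old coordinates and
#' must not overlap (enforced at ledger construction).
#'
#' @param asm An `assembly` in old coordinates.
#' @param ledger A `patch_ledger`.
#' @return A new `assembly`.
#' @export
apply_patches <- function(asm, ledger) {
  if (nrow(ledger) == 0L) return(asm)
  w <- asm_widths(asm)
  fail_if(!all(ledger$chrom %in% names(w)), "ledger references unknown chromosome")
  bad <- ledger$end > w[ledger$chrom]
  fail_if(any(bad), "edit beyond chromosome end on %s",
          paste(unique(ledger$chrom[bad]), collapse = ","))
  seqs <- as.character(asm$seqs)
  for (nm in unique(ledger$chrom)) {
    e <- ledger[ledger$chrom == nm, , drop = FALSE]
    old <- seqs[[nm]]
    # splice right-to-left so earlier coordinates stay valid
    for (i in rev(seq_len(nrow(e)))) {
      old <- paste0(substr(old, 1L, e$start[i]),
                    e$replacement[i],
                    substr(old, e$end[i] + 1L, nchar(old)))
    }
    seqs[[nm]] <- old
  }
  assembly(stats::setNames(as.character(seqs), names(seqs)), category = asm$category)
}

#' Lift old-assembly positions to new-assembly coordinates
#'
#' Positions left of every edit are unchanged; positions right of an edit
#' shift by the cumulative net length change of the edits before them.
#' Positions inside a replaced interval cannot be lifted exactly: they are
#' flagged and returned with the enclosing new interval.
#'
#' @param ledger A `patch_ledger`.
#' @param chrom Chromosome name (must appear in the ledger or be lift-neutral;
#'   unknown chromosomes are an error unless `strict = FALSE`).
#' @param pos Integer vector of 0-based positions in old coordinates.
#' @param chrom_len Optional old chromosome length for bounds checking.
#' @param strict Error on a chromosome absent from the ledger (default TRUE;
#'   with FALSE such positions lift unchanged).
#' @return A data.frame with columns `old_pos`, `new_pos` (NA when inside an
#'   edit), `inside_edit` (logical), `edit_new_start`, `edit_new_end` (the
#'   enclosing new interval when inside an edit, else NA).
#' @export
lift_coordinates <- function(ledger, chrom, pos, chrom_len = NULL, strict = TRUE) {
  e <- ledger[ledger$chrom == chrom, , drop = FALSE]
  if (nrow(e) == 0L && strict)
    stop(sprintf("chromosome '%s' not present in ledger", chrom), call. = FALSE)
  if (!is.null(chrom_len)) fail_if(any(pos < 0 | pos >= chrom_len),
                                   "position outside old chromosome length")
  delta <- e$new_len - (e$end - e$start)
  cumdelta <- c(0, cumsum(delta))
  res <- data.frame(old_pos = pos, new_pos = NA_real_, inside_edit = FALSE,
                    edit_new_start = NA_real_, edit_new_end = NA_real_)
  for (j in seq_along(pos)) {
    p <- pos[j]
    k <- findInterval(p, e$start)        # edits with start <= p
    if (k > 0L && p < e$end[k]) {        # inside edit k
      new_start <- e$start[k] + cumdelta[k]
      res$inside_edit[j] <- TRUE
      res$edit_new_start[j] <- new_start
      res$edit_new_end[j] <- new_start + e$new_len[k]
    } else {
      # number of edits fully left of p
      nleft <- sum(e$end <= p)
      res$new_pos[j] <- p + cumdelta[nleft + 1L]
    }
  }
  res
}

#' Lift an old interval to new coordinates
#'
#' Convenience wrapper mapping `[start, end)` endpoints through
#' [lift_coordinates()]; endpoints inside an edit snap outward to the edit's
#' new boundary so the result always contains the lifted material.
#'
#' @inheritParams lift_coordinates
#' @param start,end 0-based half-open old interval.
#' @return numeric `c(start, end)` in new coordinates.
#' @export
lift_interval <- function(ledger, chrom, start, end, strict = TRUE) {
  ls <- lift_coordinates(ledger, chrom, start, strict = strict)
  le <- lift_coordinates(ledger, chrom, end - 1L, strict = strict)
  s <- if (ls$inside_edit[1]) ls$edit_new_start[1] else ls$new_pos[1]
  e <- if (le$inside_edit[1]) le$edit_new_end[1] else le$new_pos[1] + 1
  c(s, e)
}

#' New-assembly intervals of all ledger fills
#'
#' @param ledger A `patch_ledger`.
#' @return data.frame `chrom`, `new_start`, `new_end`, `fill_source`, `kind`
#'   (0-based half-open, new coordinates). Zero-length replacements are kept
#'   with `new_end == new_start`.
#' @export
ledger_fill_intervals <- function(ledger) {
  if (nrow(ledger) == 0L)
    return(data.frame(chrom = character(), new_start = numeric(),
                      new_end = numeric(), fill_source = character(),
                      kind = character()))
  out <- lapply(unique(ledger$chrom), function(nm) {
    e <- ledger[ledger$chrom == nm, , drop = FALSE]
    delta <- e$new_len - (e$end - e$start)
    shift <- c(0, cumsum(delta))[seq_len(nrow(e))]
    data.frame(chrom = nm, new_start = e$start + shift,
               new_end = e$start + shift + e$new_len,
               fill_source = e$fill_source, kind = e$kind)
  })
  do.call(rbind, out)
}

#' Write / read a ledger as an AGP-like TSV
#'
#' Columns: chrom, old_start, old_end (0-based half-open), new_len,
#' fill_source, kind, replacement. The replacement sequence is stored so that
#' the ledger alone reproduces the new assembly from the old one.
#'
#' @param ledger A `patch_ledger`.
#' @param path File path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger)[, c("chrom", "start", "end", "new_len",
                                               "fill_source", "kind", "replacement")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "integer",
                                        "integer", "character", "character",
                                        "character"), na.strings = "NA")
  x$replacement[is.na(x$replacement)] <- ""
  patch_ledger(x$chrom, x$start, x$end, x$replacement, x$fill_source, x$kind)
}

#' Export closed-gap intervals as BED
#'
#' BED of the ledger's fill intervals in new-assembly coordinates
#' (0-based half-open, matching BED).
#'
#' @param ledger A `patch_ledger`.
#' @param path Output BED path.
#' @export
write_fills_bed <- function(ledger, path) {
  iv <- ledger_fill_intervals(ledger)
  utils::write.table(data.frame(iv$chrom, format(iv$new_start, scientific = FALSE, trim = TRUE),
                                format(iv$new_end, scientific = FALSE, trim = TRUE),
                                ifelse(is.na(iv$fill_source), ".", iv$fill_source)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
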