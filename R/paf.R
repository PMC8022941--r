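# PAF alignment parsing and the threshold filters every downstream rule
# builds on. Alignment blocks are stored as a plain data.frame: one row per
# pairwise alignment with 0-based half-open query/target intervals, strand,
# match counts and an identity fraction (col 10 / col 11 of PAF).

paf_cols <- c("query", "q_len", "q_start", "q_end", "strand",
              "target", "t_len", "t_start", "t_end", "matches", "block_len")

empty_blocks <- function() {
  data.frame(query = character(), q_len = numeric(), q_start = numeric(),
             q_end = numeric(), strand = character(), target = character(),
             t_len = numeric(), t_start = numeric(), t_end = numeric(),
             matches = numeric(), block_len = numeric(), identity = numeric(),
             is_primary = logical(), stringsAsFactors = FALSE)
}

#' Parse PAF alignments
#'
#' Reads minimap2-dialect PAF. The first 12 columns are required; optional
#' SAM-like tags are scanned for `tp:A:` to set the primary flag (`tp:A:P`
#' and `tp:A:I` are primary; `tp:A:S` secondary; absent tag means primary).
#' Malformed lines are skipped with a warning reporting the count.
#'
#' @param path A PAF file path, or a character vector of PAF lines.
#' @return data.frame of alignment blocks with columns `query`, `q_len`,
#'   `q_start`, `q_end`, `strand`, `target`, `t_len`, `t_start`, `t_end`,
#'   `matches`, `block_len`, `identity`, `is_primary`. Coordinates are
#'   0-based half-open as in PAF.
#' @export
parse_paf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 12L && f[5] %in% c("+", "-") &&
      !anyNA(suppressWarnings(as.numeric(f[c(2:4, 7:12)])))
  }, logical(1))
  if (any(!ok)) warning(sprintf("parse_paf: skipped %d malformed line(s)", sum(!ok)),
                        call. = FALSE)
  fields <- fields[ok]
  if (length(fields) == 0L) return(empty_blocks())
  get_chr <- function(i) vapply(fields, `[[`, character(1), i)
  get_num <- function(i) as.numeric(get_chr(i))
  tp <- vapply(fields, function(f) {
    tag <- grep("^tp:A:", f[-(1:12)], value = TRUE)
    if (length(tag) == 0L) "P" else substring(tag[1], 6L, 6L)
  }, character(1))
  out <- data.frame(query = get_chr(1), q_len = get_num(2),
                    q_start = get_num(3), q_end = get_num(4),
                    strand = get_chr(5),
                    target = get_chr(6), t_len = get_num(7),
                    t_start = get_num(8), t_end = get_num(9),
                    matches = get_num(10), block_len = get_num(11),
                    stringsAsFactors = FALSE)
  out$identity <- ifelse(out$block_len > 0, out$matches / out$block_len, 0)
  out$is_primary <- tp %in% c("P", "I")
  out
}

#' Write alignment blocks as PAF
#'
#' Inverse of [parse_paf()] for the 12 mandatory columns plus a `tp:A` tag.
#'
#' @param blocks Alignment-block data.frame.
#' @param path Output path.
#' @export
write_paf <- function(blocks, path) {
  # sequence lengths may be unknown for constructed blocks; PAF needs a number
  blocks$q_len[is.na(blocks$q_len)] <- 0
  blocks$t_len[is.na(blocks$t_len)] <- 0
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(blocks$query, fmt(blocks$q_len), fmt(blocks$q_start),
                 fmt(blocks$q_end), blocks$strand, blocks$target,
                 fmt(blocks$t_len), fmt(blocks$t_start), fmt(blocks$t_end),
                 fmt(blocks$matches), fmt(blocks$block_len), "255",
                 paste0("tp:A:", ifelse(blocks$is_primary, "P", "S")),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Collinearity filter on alignment blocks
#'
#' Keeps blocks whose identity is strictly greater than `min_identity` and
#' whose target span is strictly greater than `min_len` (both strict,
#' matching a "greater than" filter convention).
#'
#' @param blocks Alignment-block data.frame.
#' @param min_identity Identity fraction threshold in (0, 1] (default 0.98).
#' @param min_len Target span threshold in bp (default 4000).
#' @return The retained subset, same columns.
#' @export
filter_collinear <- function(blocks, min_identity = 0.98, min_len = 4000) {
  fail_if(min_identity <= 0 || min_identity > 1, "min_identity must be in (0,1]")
  fail_if(min_len < 1, "min_len must be >= 1 bp")
  keep <- blocks$identity > min_identity & (blocks$t_end - blocks$t_start) > min_len
  blocks[keep, , drop = FALSE]
}

#' Uniquely aligned query span within a target region
#'
#' For one query, counts the query bases covered by exactly one primary
#' alignment block, restricted to blocks whose target interval intersects
#' `target_region`. Bases covered by two or more primary blocks anywhere are
#' not unique and never count.
#'
#' @param blocks Blocks of a single query (secondary blocks are dropped).
#' @param target_chrom,target_start,target_end The target region
#'   (0-based half-open). `NULL` chrom means any target.
#' @return Number of uniquely aligned query bases (numeric).
#' @export
unique_anchor_span <- function(blocks, target_chrom = NULL,
                               target_start = -Inf, target_end = Inf) {
  blocks <- blocks[blocks$is_primary, , drop = FALSE]
  if (nrow(blocks) == 0L) return(0)
  fail_if(length(unique(blocks$query)) > 1L,
          "unique_anchor_span expects blocks of a single query")
  # multiplicity over the query from ALL primary blocks
  ir_all <- IRanges::IRanges(start = blocks$q_start + 1L, end = blocks$q_end)
  cov <- IRanges::coverage(ir_all)
  in_region <- (is.null(target_chrom) | blocks$target == target_chrom) &
    blocks$t_start < target_end & blocks$t_end > target_start
  if (!any(in_region)) return(0)
  ir_reg <- IRanges::reduce(IRanges::IRanges(start = blocks$q_start[in_region] + 1L,
                                             end = blocks$q_end[in_region]))
  # unique positions: coverage exactly 1
  uniq <- methods::as(IRanges::slice(cov, lower = 1L, upper = 1L), "IRanges")
  sum(IRanges::width(IRanges::intersect(uniq, ir_reg)))
}

#' Stringent whole-query placement filter
#'
#' Decides whether a query sequence is confidently placed at a single target
#' locus: some locus must account for at least `min_q_frac` of the query
#' length in aligned bases, with a mismatch fraction over the aligned region
#' of at most `max_mismatch` (both inclusive). Blocks on one target separated
#' by more than `locus_gap` bp are treated as distinct loci. Ties are broken
#' by most aligned bases, then lowest mismatch fraction, then lexicographic
#' target name.
#'
#' The mismatch fraction is computed as
#' (aligned query bases - matches) / aligned query bases, a BLAT-style
#' accounting dialect.
#'
#' @param blocks Blocks of a single query.
#' @param query_len Query length in bp (> 0).
#' @param min_q_frac Minimum aligned fraction of the query (default 0.9).
#' @param max_mismatch Maximum mismatch fraction (default 0.02).
#' @param locus_gap Max target-gap joining blocks into one locus (default 50 kb).
#' @return list `placed` (logical), `target`, `t_start`, `t_end`,
#'   `aligned_bases`, `mismatch_frac` of the best locus (NA when no block).
#' @export
placement_filter <- function(blocks, query_len, min_q_frac = 0.9,
                             max_mismatch = 0.02, locus_gap = 50000) {
  fail_if(query_len <= 0, "query_len must be > 0")
  if (nrow(blocks) == 0L)
    return(list(placed = FALSE, target = NA_character_, t_start = NA_real_,
                t_end = NA_real_, aligned_bases = 0, mismatch_frac = NA_real_))
  loci <- list()
  for (tg in sort(unique(blocks$target))) {
    b <- blocks[blocks$target == tg, , drop = FALSE]
    b <- b[order(b$t_start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(b$t_start[-1] - cummax(b$t_end)[-nrow(b)] > locus_gap)))
    for (g in unique(grp)) {
      bb <- b[grp == g, , drop = FALSE]
      qcov <- IRanges::reduce(IRanges::IRanges(bb$q_start + 1L, bb$q_end))
      aligned <- sum(IRanges::width(qcov))
      mm <- max(0, aligned - sum(bb$matches)) / aligned
      loci[[length(loci) + 1L]] <- data.frame(
        target = tg, t_start = min(bb$t_start), t_end = max(bb$t_end),
        aligned_bases = aligned, mismatch_frac = mm, stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, loci)
  loci <- loci[order(-loci$aligned_bases, loci$mismatch_frac, loci$target), , drop = FALSE]
  best <- loci[1L, ]
  placed <- best$aligned_bases >= min_q_frac * query_len &&
    best$mismatch_frac <= max_mismatch
  list(placed = placed, target = best$target, t_start = best$t_start,
       t_end = best$t_end, aligned_bases = best$aligned_bases,
       mismatch_frac = best$mismatch_frac)
}
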