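# Independent oracles used to check the implementation by a different route.
# These deliberately use naive algorithms (character scans, per-base counts,
# exhaustive scoring) so a bug in the package path cannot hide in the oracle.

# exhaustive character-scan gap finder
oracle_find_gaps <- function(seq, min_run = 1L) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  runs <- rle(v == "N")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values & runs$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

# naive re-splice: apply edits one at a time, recomputing coordinates from
# scratch by rebuilding the string left to right
oracle_splice <- function(seq, starts, ends, fills) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; fills <- fills[o]
  out <- ""
  cursor <- 0L
  for (i in seq_along(starts)) {
    out <- paste0(out, substr(seq, cursor + 1L, starts[i]), fills[i])
    cursor <- ends[i]
  }
  paste0(out, substr(seq, cursor + 1L, nchar(seq)))
}

# cumulative-sum N50/L50
oracle_n50 <- function(lens, frac = 0.5) {
  lens <- sort(lens, decreasing = TRUE)
  i <- which(cumsum(lens) >= frac * sum(lens))[1]
  list(n = lens[i], l = i)
}

# per-base multiplicity count of uniquely covered query bases restricted to
# blocks intersecting the region
oracle_unique_span <- function(blocks, chrom, rs, re) {
  b <- blocks[blocks$is_primary, , drop = FALSE]
  if (nrow(b) == 0L) return(0)
  qmax <- max(b$q_end)
  mult <- integer(qmax)
  for (i in seq_len(nrow(b))) {
    idx <- (b$q_start[i] + 1L):b$q_end[i]
    mult[idx] <- mult[idx] + 1L
  }
  inreg <- logical(qmax)
  sel <- b$target == chrom & b$t_start < re & b$t_end > rs
  for (i in which(sel)) inreg[(b$q_start[i] + 1L):b$q_end[i]] <- TRUE
  sum(mult == 1L & inreg)
}

# per-base pileup depth
oracle_depth <- function(starts, ends, len) {
  d <- integer(len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):min(ends[i], len)
    d[idx] <- d[idx] + 1L
  }
  d
}

# exhaustive HOR period scoring on plain identity of equal-length monomers
oracle_hor_scores <- function(mons) {
  n <- length(mons)
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  vapply(seq_len(floor(n / 3)), function(p) {
    mean(vapply(seq_len(n - p), function(i) ident(mons[i], mons[i + p]),
                numeric(1)))
  }, numeric(1))
}

# brute-force pairwise feature-vs-segment intersection count
oracle_overlap_count <- function(segments, features) {
  hit <- 0L
  for (i in seq_len(nrow(features))) {
    for (k in seq_len(nrow(segments))) {
      if (features$chrom[i] == segments$chrom[k] &&
          features$start[i] < segments$end[k] &&
          features$end[i] > segments$start[k]) { hit <- hit + 1L; break }
    }
  }
  hit
}

# IRanges-based base overlap (independent route from the base-R package code)
oracle_base_overlap <- function(segments, features) {
  total <- 0
  for (nm in unique(segments$chrom)) {
    s <- segments[segments$chrom == nm, , drop = FALSE]
    f <- features[features$chrom == nm, , drop = FALSE]
    if (nrow(f) == 0L) next
    si <- IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))
    fi <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    total <- total + sum(IRanges::width(IRanges::intersect(si, fi)))
  }
  total
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
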