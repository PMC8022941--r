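# Permutation enrichment tests: are the newly added (gap-fill) intervals
# richer in repeats / gene bases than length-matched segments drawn at
# random from the chromosomes? The null distribution shuffles the observed
# segment-length multiset uniformly over chromosome space, avoiding excluded
# intervals (e.g. remaining gaps), without self-overlap.

#' Randomly place segments across a genome
#'
#' Each segment length is placed uniformly at random among all genome
#' positions where the segment fits entirely inside one chromosome without
#' touching an excluded interval or a previously placed segment. Placement
#' is retried a bounded number of times before erroring.
#'
#' @param lengths Integer vector of segment lengths to place.
#' @param genome data.frame `chrom`, `length` (chromosomes only).
#' @param excluded Optional data.frame `chrom`, `start`, `end` of forbidden
#'   intervals (0-based half-open).
#' @param max_retries Restarts allowed when space runs out (default 50).
#' @return data.frame `chrom`, `start`, `end`, one row per input length (in
#'   decreasing-length placement order).
#' @export
shuffle_segments <- function(lengths, genome, excluded = NULL,
                             max_retries = 50L) {
  fail_if(length(lengths) == 0L, "no segment lengths supplied")
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)  # big ones first
  base_excl <- split_excluded(excluded, genome)
  for (attempt in seq_len(max_retries)) {
    excl <- base_excl
    starts <- numeric(length(lengths)); chroms <- character(length(lengths))
    ok <- TRUE
    for (i in seq_along(lengths)) {
      pos <- draw_position(lengths[i], genome, excl)
      if (is.null(pos)) { ok <- FALSE; break }
      starts[i] <- pos$start; chroms[i] <- pos$chrom
      e <- excl[[pos$chrom]]
      excl[[pos$chrom]] <- list(s = c(e$s, pos$start), e = c(e$e, pos$start + lengths[i]))
    }
    if (ok)
      return(data.frame(chrom = chroms, start = starts, end = starts + lengths,
                        stringsAsFactors = FALSE))
  }
  stop("shuffle_segments: could not place all segments (space exhausted)",
       call. = FALSE)
}

# per-chromosome excluded intervals as plain start/end vectors (0-based
# half-open); base-R arithmetic keeps the permutation loop fast
split_excluded <- function(excluded, genome) {
  out <- stats::setNames(vector("list", nrow(genome)), genome$chrom)
  for (nm in genome$chrom) {
    if (is.null(excluded)) { out[[nm]] <- list(s = numeric(0), e = numeric(0)); next }
    ex <- excluded[excluded$chrom == nm, , drop = FALSE]
    out[[nm]] <- list(s = as.numeric(ex$start), e = as.numeric(ex$end))
  }
  out
}

# merge possibly-overlapping intervals
reduce_ivls <- function(iv) {
  if (length(iv$s) == 0L) return(iv)
  o <- order(iv$s)
  s <- iv$s[o]; e <- iv$e[o]
  run_e <- cummax(e)
  new_run <- c(TRUE, s[-1] > run_e[-length(s)])
  grp <- cumsum(new_run)
  list(s = s[new_run], e = as.numeric(tapply(e, grp, max)))
}

# uniform draw of one segment start over all allowed slots genome-wide
draw_position <- function(len, genome, excl) {
  slot_chrom <- character(0); slot_start <- numeric(0); slot_n <- numeric(0)
  for (i in seq_len(nrow(genome))) {
    nm <- genome$chrom[i]
    red <- reduce_ivls(excl[[nm]])
    allow_s <- c(0, red$e); allow_e <- c(red$s, genome$length[i])
    w <- allow_e - allow_s - len + 1
    keep <- w > 0
    if (any(keep)) {
      slot_chrom <- c(slot_chrom, rep(nm, sum(keep)))
      slot_start <- c(slot_start, allow_s[keep])
      slot_n <- c(slot_n, w[keep])
    }
  }
  total <- sum(slot_n)
  if (total <= 0) return(NULL)
  u <- sample.int(total, 1L)
  cum <- cumsum(slot_n)
  row <- which(cum >= u)[1L]
  offset <- u - c(0, cum)[row] - 1L
  start <- slot_start[row] + offset
  list(chrom = slot_chrom[row], start = start, end = start + len)
}

#' Count features intersecting any segment
#'
#' A feature counts once when it overlaps at least one segment by >= 1 bp
#' (half-open abutment is not an overlap).
#'
#' @param segments,features data.frames `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Integer count of intersecting features.
#' @export
overlap_count <- function(segments, features) {
  if (nrow(features) == 0L || nrow(segments) == 0L) return(0L)
  hit <- logical(nrow(features))
  for (nm in unique(features$chrom)) {
    fi <- which(features$chrom == nm)
    s <- segments[segments$chrom == nm, , drop = FALSE]
    if (nrow(s) == 0L) next
    for (k in seq_len(nrow(s))) {
      hit[fi] <- hit[fi] | (features$start[fi] < s$end[k] &
                              features$end[fi] > s$start[k])
    }
  }
  sum(hit)
}

#' Bases of segments overlapped by features
#'
#' Total bases in the intersection of the segments with the union of the
#' features (nested/overlapping features counted once).
#'
#' @inheritParams overlap_count
#' @return Numeric base count.
#' @export
base_overlap <- function(segments, features) {
  if (nrow(features) == 0L || nrow(segments) == 0L) return(0)
  total <- 0
  for (nm in unique(segments$chrom)) {
    s <- segments[segments$chrom == nm, , drop = FALSE]
    f <- features[features$chrom == nm, , drop = FALSE]
    if (nrow(f) == 0L) next
    fu <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    fs <- IRanges::start(fu) - 1L; fe <- IRanges::end(fu)
    for (k in seq_len(nrow(s))) {
      total <- total + sum(ivl_overlap(s$start[k], s$end[k], fs, fe))
    }
  }
  total
}

#' Permutation test of feature enrichment in observed segments
#'
#' Compares the observed statistic (feature count or overlapping bases) in
#' the observed segments to `n_perm` random placements of the same segment
#' length multiset. Empirical p-values use the add-one correction, so the
#' smallest attainable p is 1/(n_perm+1).
#'
#' @param observed_segments data.frame `chrom`, `start`, `end`.
#' @param features data.frame `chrom`, `start`, `end`.
#' @param genome data.frame `chrom`, `length`.
#' @param excluded Optional forbidden intervals for the null placements.
#' @param statistic `"count"` or `"bases"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed for reproducible draws.
#' @return list of class `enrichment_result`: `observed`, `null_draws`,
#'   `p_enriched`, `p_depleted`, `p_value` (the smaller tail), `direction`,
#'   `statistic`, `n_perm`, `seed`.
#' @export
permutation_test <- function(observed_segments, features, genome,
                             excluded = NULL, statistic = c("count", "bases"),
                             n_perm = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  fail_if(n_perm < 1L, "n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (statistic == "count") overlap_count else base_overlap
  obs <- stat_fun(observed_segments, features)
  lens <- observed_segments$end - observed_segments$start
  null_draws <- vapply(seq_len(n_perm), function(k) {
    seg <- shuffle_segments(lens, genome, excluded)
    stat_fun(seg, features)
  }, numeric(1))
  p_enr <- (1 + sum(null_draws >= obs)) / (n_perm + 1)
  p_dep <- (1 + sum(null_draws <= obs)) / (n_perm + 1)
  structure(list(observed = obs, null_draws = null_draws,
                 p_enriched = p_enr, p_depleted = p_dep,
                 p_value = min(p_enr, p_dep),
                 direction = if (p_enr <= p_dep) "enriched" else "depleted",
                 statistic = statistic, n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> statistic=%s observed=%g direction=%s p=%.4g (enriched %.4g / depleted %.4g; %d permutations)\n",
              x$statistic, x$observed, x$direction, x$p_value,
              x$p_enriched, x$p_depleted, x$n_perm))
  invisible(x)
}
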