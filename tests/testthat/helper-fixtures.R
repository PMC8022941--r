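# Shared fixtures built in code. The heavyweight simulated genome bundles
# are built once per test run and memoised.

# a tiny hand-built assembly used across the genome-model tests
tiny_assembly <- function() {
  assembly(c(chrA = "ACGTNNNNACGT",
             chrB = "NNNNACGTACGTACGTNNACG",
             chrUn_x = "ACGTNNNNACGT"))
}

.fixture_cache <- new.env(parent = emptyenv())

# default error-free fixture (no anomalies, no reads)
default_fixture <- function() {
  if (is.null(.fixture_cache$clean)) {
    .fixture_cache$clean <- simulate_fixture(sim_config(seed = 1),
                                             with_reads = FALSE)
  }
  .fixture_cache$clean
}

# anomalous fixture with linked reads: one translocation, one non-linear
# homology donor, one uncovered fill, one mis-joined scaffold contig
anomaly_fixture <- function() {
  if (is.null(.fixture_cache$anom)) {
    cfg <- sim_config(seed = 2, anomalies = list(translocated_fill = 1,
                                                 nonlinear_homology = 1,
                                                 uncovered_fill = 1,
                                                 misjoined_contig = 1))
    .fixture_cache$anom <- simulate_fixture(cfg, with_reads = TRUE)
  }
  .fixture_cache$anom
}

# run the gap-filling pass on a fixture (memoised alongside it)
fixture_gapfill <- function(fx, key) {
  slot <- paste0(key, "_fill")
  if (is.null(.fixture_cache[[slot]])) {
    gaps <- find_gaps(fx$deg$reference)
    .fixture_cache[[slot]] <- run_gapfill(fx$deg$reference, gaps,
                                          fx$donors$donors, fx$donors$paf)
  }
  .fixture_cache[[slot]]
}

# locate each fill sequence in the truth genome by exact matching: the
# independent-assembly alignment a collinearity check would consume.
# Returns parse_paf-shaped blocks (one per located fill).
fills_to_truth_blocks <- function(ledger, truth_asm) {
  rows <- list()
  truth <- truth_asm$seqs
  led <- as.data.frame(ledger)
  led <- led[nchar(led$replacement) > 0, , drop = FALSE]
  for (i in seq_len(nrow(led))) {
    fill <- Biostrings::DNAString(led$replacement[i])
    qname <- sprintf("fill_%s_%d", led$chrom[i], led$start[i])
    for (nm in names(truth)) {
      hits <- Biostrings::matchPattern(fill, truth[[nm]])
      if (length(hits) == 0L)
        hits <- Biostrings::matchPattern(Biostrings::reverseComplement(fill),
                                         truth[[nm]])
      if (length(hits) > 0L) {
        w <- nchar(led$replacement[i])
        rows[[length(rows) + 1L]] <- data.frame(
          query = qname, q_len = w, q_start = 0L, q_end = w, strand = "+",
          target = nm, t_len = length(truth[[nm]]),
          t_start = Biostrings::start(hits)[1] - 1L,
          t_end = Biostrings::end(hits)[1], matches = w, block_len = w,
          identity = 1, is_primary = TRUE, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), q_len = numeric(), q_start = numeric(),
               q_end = numeric(), strand = character(), target = character(),
               t_len = numeric(), t_start = numeric(), t_end = numeric(),
               matches = numeric(), block_len = numeric(),
               identity = numeric(), is_primary = logical())
}

# fill table (fill_id + chromosome) matching fills_to_truth_blocks naming
ledger_fill_table <- function(ledger) {
  led <- as.data.frame(ledger)
  led <- led[nchar(led$replacement) > 0, , drop = FALSE]
  data.frame(fill_id = sprintf("fill_%s_%d", led$chrom, led$start),
             chrom = led$chrom, stringsAsFactors = FALSE)
}

# one-row anchor block constructor for gap-filler unit tests
mk_block <- function(query, q_start, q_end, strand, target, t_start, t_end,
                     identity = 1, q_len = NA_real_) {
  w <- q_end - q_start
  data.frame(query = query, q_len = q_len, q_start = q_start, q_end = q_end,
             strand = strand, target = target, t_len = NA_real_,
             t_start = t_start, t_end = t_end, matches = round(identity * w),
             block_len = w, identity = identity, is_primary = TRUE,
             stringsAsFactors = FALSE)
}
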