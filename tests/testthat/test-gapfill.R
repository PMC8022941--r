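# Gap closing: anchoring, deviation rule, partial fills, shrinkage guard.

# hand-built single-gap genome: 30 bp flank + 12 N + 30 bp flank
gap_genome <- function(gap_n = 12, fill_true = "ACGTACGTACGT") {
  left <- strrep("ACGTTGCAAGTC", 5)     # 60 bp of left flank
  right <- strrep("TTGACCAGTCAA", 5)
  ref <- paste0(left, strrep("N", gap_n), right)
  truth <- paste0(left, fill_true, right)
  list(ref = assembly(c(c1 = ref)), truth = truth, left = left, right = right,
       gap = data.frame(chrom = "c1", start = nchar(left),
                        end = nchar(left) + gap_n))
}

test_that("anchor_contigs pairs flank-proximal blocks and respects the window", {
  g <- gap_genome()
  blocks <- rbind(
    mk_block("d1", 0, 50, "+", "c1", 10, 60),        # ends at gap start
    mk_block("d1", 70, 120, "+", "c1", 72, 122),     # starts at gap end
    mk_block("far", 0, 50, "+", "c1", 0, 5))         # ends 55 bp before gap
  anc <- anchor_contigs(g$gap, blocks, flank = 10)
  expect_equal(anc$left$query, "d1")
  expect_equal(anc$right$query, "d1")
  anc2 <- anchor_contigs(g$gap, blocks, flank = 60)
  expect_true("far" %in% anc2$left$query)
})

test_that("close_gap splices the donor fill on both strands, bit-exactly", {
  g <- gap_genome()
  donor <- paste0(g$left, "ACGTACGTACGT", g$right)
  left_b <- mk_block("d", 0, 60, "+", "c1", 0, 60)
  right_b <- mk_block("d", 72, 132, "+", "c1", 72, 132)
  cl <- close_gap(left_b, right_b, donor, g$gap, a = 1)
  expect_equal(cl$outcome, "closed")
  expect_equal(cl$replacement, "ACGTACGTACGT")
  expect_equal(cl$deviation, 0)
  # minus-strand donor: same fill after reverse complement
  donor_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(donor)))
  dlen <- nchar(donor)
  left_rc <- mk_block("d", dlen - 60, dlen, "-", "c1", 0, 60)
  right_rc <- mk_block("d", 0, 60, "-", "c1", 72, 132)
  cl2 <- close_gap(left_rc, right_rc, donor_rc, g$gap, a = 1)
  expect_equal(cl2$outcome, "closed")
  expect_equal(cl2$replacement, "ACGTACGTACGT")
  # patched locus is bit-identical to the truth sequence
  led <- patch_ledger(cl$chrom, cl$edit_start, cl$edit_end, cl$replacement)
  expect_equal(as.character(apply_patches(g$ref, led)$seqs[[1]]), g$truth)
})

test_that("close_gap applies the deviation tolerance", {
  # gap 400, fill 340, a=1 -> deviation 0.15 -> closed
  left <- strrep("ACGTTGCAAGTC", 500); right <- strrep("TTGACCAGTCAA", 500)
  fill <- random_seq(340)
  gap <- data.frame(chrom = "c1", start = 6000, end = 6400)
  donor <- paste0(substr(left, 1, 6000), fill, right)
  lb <- mk_block("d", 0, 6000, "+", "c1", 0, 6000)
  rb <- mk_block("d", 6340, 6340 + 6000, "+", "c1", 6400, 12400)
  cl <- close_gap(lb, rb, donor, gap, a = 1)
  expect_equal(cl$outcome, "closed")
  expect_equal(cl$deviation, 0.15)
  # gap 400, fill 900 -> deviation 1.25 -> rejected
  fill9 <- random_seq(900)
  donor9 <- paste0(substr(left, 1, 6000), fill9, right)
  rb9 <- mk_block("d", 6900, 6900 + 6000, "+", "c1", 6400, 12400)
  cl9 <- close_gap(lb, rb9, donor9, gap, a = 1)
  expect_equal(cl9$outcome, "rejected_deviation")
  expect_equal(cl9$deviation, 1.25)
  # inconsistent strands are a caller error
  rb_minus <- rb; rb_minus$strand <- "-"
  expect_error(close_gap(lb, rb_minus, donor, gap), "strand")
})

test_that("out-of-order anchors signal non-linear homology", {
  gap <- data.frame(chrom = "c1", start = 100, end = 110)
  lb <- mk_block("d", 500, 600, "+", "c1", 0, 100)
  rb <- mk_block("d", 0, 100, "+", "c1", 110, 210)
  expect_equal(close_gap(lb, rb, random_seq(600), gap)$outcome,
               "rejected_order")
})

test_that("extend_gap inserts capped overhangs from one side", {
  g <- gap_genome(gap_n = 400)
  # donor carries the left flank plus 120 bp of overhang into the gap
  donor <- paste0(g$left, random_seq(120))
  anchor <- mk_block("d", 0, 60, "+", "c1", 0, 60)
  p <- extend_gap(anchor, "left", donor, g$gap)
  expect_equal(p$outcome, "partial_left")
  expect_equal(p$fill_len, 120)
  expect_equal(p$added_bases, 120)
  # 280 N must remain at the locus after patching
  led <- patch_ledger(p$chrom, p$edit_start, p$edit_end, p$replacement)
  patched <- as.character(apply_patches(g$ref, led)$seqs[[1]])
  expect_equal(nchar(gsub("[^N]", "", patched)), 280)
  # overhang 500 > gap 400 -> capped at 400
  donor2 <- paste0(g$left, random_seq(500))
  p2 <- extend_gap(anchor, "left", donor2, g$gap)
  expect_equal(p2$fill_len, 400)
  # zero overhang -> unfilled
  p3 <- extend_gap(anchor, "left", g$left, g$gap)
  expect_equal(p3$outcome, "unfilled")
})

test_that("shrinkage_guard rejects flank-deleting fills and passes the rest", {
  gap <- data.frame(chrom = "c1", start = 100, end = 500)
  ordinary <- closure_ok <- close_gap(
    mk_block("d", 0, 100, "+", "c1", 0, 100),
    mk_block("d", 500, 600, "+", "c1", 500, 600),
    random_seq(600), gap, a = 1)
  expect_equal(ordinary$outcome, "closed")
  # anchors whose gap-boundary images cross: negative fill
  lb <- mk_block("d", 0, 80, "+", "c1", 0, 80)      # ends 20 bp before gap
  rb <- mk_block("d", 90, 170, "+", "c1", 520, 600) # starts 20 bp after gap
  shr <- close_gap(lb, rb, random_seq(170), gap, a = 1)
  expect_equal(shr$outcome, "shrinkage_candidate")
  guard <- shrinkage_guard(rbind(ordinary, shr))
  expect_equal(nrow(guard$accepted), 1L)
  expect_equal(guard$rejected$outcome, "rejected_shrinkage")
})

test_that("run_gapfill with no alignments leaves every gap unfilled", {
  fx <- default_fixture()
  gaps <- find_gaps(fx$deg$reference)
  res <- run_gapfill(fx$deg$reference, gaps, fx$donors$donors,
                     fx$donors$paf[0, ])
  expect_equal(res$counts$closed, 0)
  expect_equal(res$counts$unfilled, nrow(gaps))
  expect_equal(nrow(res$ledger), 0L)
})

test_that("run_gapfill report partitions the gap set", {
  fx <- default_fixture()
  res <- fixture_gapfill(fx, "clean")
  gaps <- find_gaps(fx$deg$reference)
  expect_equal(nrow(res$report), nrow(gaps))
  cnt <- res$counts
  expect_equal(cnt$closed + cnt$partial_left + cnt$partial_right +
                 cnt$unfilled + cnt$rejected_deviation +
                 cnt$rejected_shrinkage + cnt$rejected_order, nrow(gaps))
})

test_that("contig N50 never decreases under gap filling", {
  fx <- default_fixture()
  res <- fixture_gapfill(fx, "clean")
  before <- contiguity_metrics(fx$deg$reference)
  after <- contiguity_metrics(apply_patches(fx$deg$reference, res$ledger))
  expect_gte(after$contig_N50, before$contig_N50)
  expect_lte(after$n_gaps, before$n_gaps)
})
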