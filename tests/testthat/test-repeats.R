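# Telomere motif scanning/merging and centromere monomer arrays.

test_that("count_motif counts non-overlapping case-insensitive matches", {
  expect_equal(count_motif(strrep("TTAGGG", 60), "TTAGGG"), 60)
  expect_equal(count_motif(strrep("ttaggg", 50), "TTAGGG"), 50)
  expect_equal(count_motif("ACGT", "TTAGGG"), 0)
  # non-overlapping: AAAA contains two AA, not three
  expect_equal(count_motif("AAAA", "AA"), 2)
  expect_error(count_motif("ACGT", ""), "non-empty")
})

test_that("forward motif count equals reverse motif count after revcomp", {
  set.seed(21)
  for (k in 1:100) {
    s <- paste0(random_seq(sample(50:300, 1)),
                strrep("TTAGGG", sample(0:10, 1)), random_seq(50))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(count_motif(s, "TTAGGG"), count_motif(rc, "CCCTAA"))
    expect_equal(count_motif(s, "CCCTAA"), count_motif(rc, "TTAGGG"))
  }
})

test_that("select_telomeric_reads applies the strict >threshold rule", {
  reads <- c(hi = strrep("TTAGGG", 60), at = strrep("TTAGGG", 50),
             none = random_seq(600))
  sel <- select_telomeric_reads(reads, threshold = 50)
  expect_equal(sel$read, "hi")
  expect_equal(nrow(select_telomeric_reads(character(0) |>
                                             stats::setNames(character(0)))), 0L)
  # reverse-strand telomeric reads are selected via CCCTAA
  rc <- c(r1 = strrep("CCCTAA", 60))
  expect_equal(select_telomeric_reads(rc)$motif_count_rev, 60)
})

test_that("assign_telomere needs >10 kb unique anchor at one end only", {
  lens <- c(chr4 = 200000, chr5 = 200000)
  b12 <- mk_block("r", 0, 12000, "+", "chr4", 188000, 200000)
  a <- assign_telomere(b12, lens)
  expect_equal(a$chrom, "chr4")
  expect_equal(a$side, "right")
  expect_equal(a$unique_anchor_bp, 12000)
  # 9 kb anchor: below threshold
  b9 <- mk_block("r", 0, 9000, "+", "chr4", 191000, 200000)
  expect_null(assign_telomere(b9, lens))
  # anchors at two chromosomes: ambiguous
  b2 <- rbind(mk_block("r", 0, 12000, "+", "chr4", 188000, 200000),
              mk_block("r", 15000, 27000, "+", "chr5", 0, 12000))
  expect_null(assign_telomere(b2, lens))
})

test_that("merge_telomere appends only the unaligned overhang", {
  lens <- c(chr4 = 200000)
  tail_seq <- strrep("TTAGGG", 500)
  read <- paste0(random_seq(12000), tail_seq)
  b <- mk_block("telr", 0, 12000, "+", "chr4", 188000, 200000)
  a <- assign_telomere(b, lens)
  led <- merge_telomere(a, b, read, 200000)
  expect_equal(nrow(led), 1L)
  expect_equal(led$kind, "end_extension")
  expect_equal(led$start, 200000)
  expect_equal(led$replacement, tail_seq)
  # length grows by exactly the overhang; existing bases untouched
  asm <- assembly(c(chr4 = random_seq(200000)))
  merged <- apply_patches(asm, led)
  expect_equal(nchar(as.character(merged$seqs[[1]])), 200000 + 3000)
  expect_equal(substr(as.character(merged$seqs[[1]]), 1, 200000),
               as.character(asm$seqs[[1]]))
  # fully aligned read: nothing to add
  b_full <- mk_block("telr", 0, nchar(read), "+", "chr4",
                     200000 - nchar(read), 200000)
  a_full <- assign_telomere(b_full, lens)
  expect_null(merge_telomere(a_full, b_full, read, 200000))
})

test_that("find_monomers recovers exact tandem arrays and applies thresholds", {
  set.seed(33)
  mono <- random_seq(186)
  contig <- paste0(random_seq(500), strrep(mono, 10), random_seq(500))
  r <- find_monomers(contig, mono, min_identity = 0.8)
  expect_equal(r$monomer_count, 10L)
  expect_equal(r$array_span, 1860)
  expect_true(all(r$hits$identity == 1))
  # a 70%-identity copy is not a hit at threshold 0.8
  degraded <- local({
    v <- strsplit(mono, "")[[1]]
    idx <- sample(186, 56)
    v[idx] <- sapply(v[idx], function(b) setdiff(c("A","C","G","T"), b)[1])
    paste(v, collapse = "")
  })
  r2 <- find_monomers(paste0(random_seq(300), degraded, random_seq(300)),
                      mono, min_identity = 0.8)
  expect_equal(r2$monomer_count, 0L)
  # minus-strand arrays are found too
  rc_contig <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  r3 <- find_monomers(rc_contig, mono, min_identity = 0.8)
  expect_equal(r3$monomer_count, 10L)
  expect_true(all(r3$hits$strand == "-"))
})

test_that("hor_period detects planted periods and matches the oracle", {
  set.seed(44)
  A <- random_seq(186)
  B <- local({v <- strsplit(A, "")[[1]]
              i <- sample(186, 28)
              v[i] <- sapply(v[i], function(b) setdiff(c("A","C","G","T"), b)[1])
              paste(v, collapse = "")})
  C <- local({v <- strsplit(A, "")[[1]]
              i <- sample(186, 28)
              v[i] <- sapply(v[i], function(b) setdiff(c("A","C","G","T"), b)[2])
              paste(v, collapse = "")})
  arr <- rep(c(A, B, C), 8)
  r <- hor_period(arr)
  expect_equal(r$period, 3L)
  expect_true(r$confident)
  expect_equal(unname(r$scores), oracle_hor_scores(arr), tolerance = 1e-12)
  # perfect tandem -> period 1
  expect_equal(hor_period(rep(A, 12))$period, 1L)
  # randomized monomer order: no period should beat the margin. A longer
  # array plus a margin above the sampling noise of short-lag means keeps
  # this a sharp permutation control (see the methods vignette).
  shuf <- sample(rep(c(A, B, C), 20))
  rs <- hor_period(shuf, margin = 0.05)
  expect_equal(rs$period, 1L)
  expect_false(rs$confident)
  # the planted period survives the same wider margin
  expect_equal(hor_period(rep(c(A, B, C), 20), margin = 0.05)$period, 3L)
  # too few monomers: undefined
  expect_false(hor_period(c(A, B, C))$defined)
})

test_that("assign_centromere classifies sides and spanning contigs", {
  cen <- data.frame(chrom = "chr1", start = 100000, end = 110000)
  left <- mk_block("ctg", 0, 15000, "+", "chr1", 85000, 100000)
  expect_equal(assign_centromere(left, cen)$side, "left_of_gap")
  both <- rbind(left, mk_block("ctg", 20000, 35000, "+", "chr1", 110000, 125000))
  expect_equal(assign_centromere(both, cen)$side, "spanning")
  short <- mk_block("ctg", 0, 8000, "+", "chr1", 92000, 100000)
  expect_null(assign_centromere(short, cen))
})

test_that("fixture telomeres and centromeres are recovered end to end", {
  fx <- default_fixture()
  res <- fixture_gapfill(fx, "clean")
  v5 <- apply_patches(fx$deg$reference, res$ledger)
  tl <- find_telomeres(fx$telomere$reads, fx$telomere$paf, v5)
  got <- tl$candidates[!is.na(tl$candidates$chrom),
                       c("read", "chrom", "side")]
  expect_equal(got[order(got$read), ],
               fx$telomere$expected[order(fx$telomere$expected$read), ],
               ignore_attr = TRUE)
  # decoys are never assigned (the at-threshold one is not even selected)
  expect_false("decoy_at_threshold" %in% tl$candidates$read)
  # every planted end is extended by the true telomere sequence
  v5t <- apply_patches(v5, tl$ledger)
  tel <- fx$deg$tel_len
  truth <- as.character(fx$sim$truth$seqs)
  cen <- fx$centromere$cen_gaps_v5
  for (nm in names(truth)) {
    expected <- truth[[nm]]
    cc <- cen[cen$chrom == nm, ]
    substr(expected, tel + cc$start + 1, tel + cc$end) <-
      strrep("N", cc$end - cc$start)
    expect_identical(as.character(v5t$seqs[[nm]]), expected)
  }
  # centromere contigs: monomer counts and side assignments
  mon <- find_monomers(fx$centromere$contigs[[1]], fx$sim$cen_consensus)
  expect_equal(mon$monomer_count,
               fx$config$hor_period * fx$config$hor_copies)
  hp <- hor_period(monomer_sequences(fx$centromere$contigs[[1]], mon$hits))
  expect_equal(hp$period, fx$config$hor_period)
  for (i in seq_len(nrow(fx$centromere$expected))) {
    b <- fx$centromere$paf[
      fx$centromere$paf$query == fx$centromere$expected$contig[i], ]
    a <- assign_centromere(b, fx$centromere$cen_gaps_v5)
    expect_equal(a$chrom, fx$centromere$expected$chrom[i])
    expect_equal(a$side, fx$centromere$expected$side[i])
  }
})
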