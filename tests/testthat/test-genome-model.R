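# Assembly container, gap detection, patching, liftover, contiguity.

test_that("find_gaps locates maximal N runs, including terminal ones", {
  asm <- tiny_assembly()
  g <- find_gaps(asm)
  expect_equal(g$chrom, c("chrA", "chrB", "chrB"))
  expect_equal(g$start, c(4, 0, 16))
  expect_equal(g$end, c(8, 4, 18))
  # unplaced sequences are never scanned
  expect_false(any(g$chrom == "chrUn_x"))
  # threshold: min_run drops short runs
  g2 <- find_gaps(assembly(c(c1 = "ACGTNACGTNNACGT")), min_run = 2)
  expect_equal(nrow(g2), 1L)
  expect_equal(c(g2$start, g2$end), c(9, 11))
  expect_error(find_gaps(asm, min_run = 0), "min_run")
})

test_that("find_gaps agrees with an exhaustive scan oracle on short strings", {
  set.seed(101)
  for (k in 1:200) {
    s <- random_seq(sample(1:20, 1), alphabet = c("A", "C", "N", "N"))
    asm <- assembly(stats::setNames(s, "c"))
    got <- find_gaps(asm, min_run = sample(1:3, 1) -> mr)
    want <- oracle_find_gaps(s, mr)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
  }
})

test_that("assembly sanitizes non-ACGTN symbols to N with a warning", {
  expect_warning(asm <- assembly(c(c1 = "ACGRYacgt")), "non-ACGTN")
  expect_equal(as.character(asm$seqs[[1]]), "ACGNNACGT")
})

test_that("apply_patches splices fills and preserves untouched sequence", {
  asm <- assembly(c(c1 = "ACGTNNNNACGT"))
  led <- patch_ledger("c1", 4, 8, "CG")
  expect_equal(as.character(apply_patches(asm, led)$seqs[[1]]), "ACGTCGACGT")
  # empty ledger is the identity
  expect_identical(as.character(apply_patches(asm, patch_ledger())$seqs),
                   as.character(asm$seqs))
  # overlapping edits are a coordinate conflict
  expect_error(patch_ledger(c("c1", "c1"), c(2, 5), c(6, 9), c("A", "A")),
               "conflict")
})

test_that("multi-edit patching equals the naive re-splice oracle", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(30:60, 1)
    s <- random_seq(n)
    n_edit <- sample(1:3, 1)
    bounds <- sort(sample(0:n, 2 * n_edit))
    starts <- bounds[seq(1, 2 * n_edit, 2)]
    ends <- bounds[seq(2, 2 * n_edit, 2)]
    keep <- ends > starts & c(TRUE, starts[-1] >= ends[-n_edit])
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    fills <- vapply(seq_along(starts), function(i) random_seq(sample(0:6, 1)),
                    character(1))
    asm <- assembly(stats::setNames(s, "c"))
    led <- patch_ledger(rep("c", length(starts)), starts, ends, fills)
    got <- as.character(apply_patches(asm, led)$seqs[[1]])
    expect_equal(got, oracle_splice(s, starts, ends, fills))
  }
})

test_that("lift_coordinates shifts, flags inside-edit positions, round-trips", {
  led <- patch_ledger("c1", 4, 8, "CG")  # [4,8) -> length 2, delta -2
  expect_equal(lift_coordinates(led, "c1", 2)$new_pos, 2)
  expect_equal(lift_coordinates(led, "c1", 10)$new_pos, 8)
  inside <- lift_coordinates(led, "c1", 5)
  expect_true(inside$inside_edit)
  expect_equal(c(inside$edit_new_start, inside$edit_new_end), c(4, 6))
  expect_error(lift_coordinates(led, "nope", 1), "not present")

  # strictly increasing outside edits; round-trip via the inverse ledger
  led2 <- patch_ledger(c("c", "c"), c(10, 30), c(20, 35), c("AAA", strrep("G", 9)))
  pos <- c(0, 5, 9, 20, 25, 29, 35, 50)
  lifted <- lift_coordinates(led2, "c", pos)$new_pos
  expect_false(anyNA(lifted))
  expect_true(all(diff(lifted) > 0))
  inv <- patch_ledger(c("c", "c"), c(10, 13 + 10), c(13, 23 + 9),
                      c(strrep("T", 10), strrep("T", 5)))
  back <- lift_coordinates(inv, "c", lifted)$new_pos
  expect_equal(back, pos)
})

test_that("contiguity metrics match the cumulative-sum oracle", {
  # single contig
  m1 <- contiguity_metrics(assembly(c(c1 = strrep("A", 10))))
  expect_equal(m1$contig_N50, 10)
  expect_equal(m1$L50, 1)
  # contig lengths {8,5,4,2,1} via one scaffold with N gaps
  s <- paste(c(strrep("A", 8), strrep("C", 5), strrep("G", 4),
               strrep("T", 2), "A"), collapse = "N")
  m2 <- contiguity_metrics(assembly(c(c1 = s)))
  expect_equal(m2$contig_N50, 5)
  expect_equal(m2$L50, 2)
  expect_equal(m2$n_gaps, 4)
  expect_equal(m2$assembly_size_no_N, 20)
  # random property vs oracle, including N90/L90 and invariants
  set.seed(11)
  for (k in 1:30) {
    lens <- sample(1:50, sample(1:8, 1), replace = TRUE)
    s <- paste(vapply(lens, strrep, character(1), x = "A"), collapse = "NN")
    m <- contiguity_metrics(assembly(c(c1 = s)))
    o50 <- oracle_n50(lens, 0.5); o90 <- oracle_n50(lens, 0.9)
    expect_equal(m$contig_N50, o50$n)
    expect_equal(m$L50, o50$l)
    expect_equal(m$contig_N90, o90$n)
    expect_equal(m$L90, o90$l)
    expect_lte(m$contig_N90, m$contig_N50)
    expect_lte(m$L50, m$L90)
  }
})

test_that("fold_change reports a 2-decimal ratio and rejects zero baselines", {
  expect_equal(fold_change(510.82, 91.68), 5.57)
  expect_equal(fold_change(3, 3), 1.00)
  expect_equal(fold_change(100, 400), 0.25)
  expect_error(fold_change(1, 0), "metric_old")
})

test_that("ledger serialization round-trips and fill intervals are correct", {
  led <- patch_ledger(c("c1", "c1", "c2"), c(4, 20, 0), c(8, 24, 0),
                      c("CG", "TTTT", "AAA"),
                      fill_source = c("d1", "d2", NA),
                      kind = c("gap_fill", "gap_fill", "end_extension"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ledger(led, path)
  led2 <- read_ledger(path)
  expect_equal(as.data.frame(led2), as.data.frame(led))
  iv <- ledger_fill_intervals(led)
  expect_equal(iv$new_start[iv$chrom == "c1"], c(4, 18))
  expect_equal(iv$new_end[iv$chrom == "c1"], c(6, 22))
})

test_that("FASTA writing and reading round-trips an assembly", {
  asm <- tiny_assembly()
  path <- withr::local_tempfile(fileext = ".fa")
  write_assembly(asm, path)
  asm2 <- read_assembly(path)
  expect_identical(as.character(asm2$seqs), as.character(asm$seqs))
  expect_identical(asm2$category, asm$category)
})
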