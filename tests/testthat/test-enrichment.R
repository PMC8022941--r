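# Segment shuffling and permutation enrichment.

toy_genome <- data.frame(chrom = c("c1", "c2"), length = c(100000, 50000))

test_that("shuffle_segments places valid, non-overlapping, length-true segments", {
  set.seed(61)
  for (k in 1:20) {
    lens <- sample(100:5000, sample(1:6, 1))
    seg <- shuffle_segments(lens, toy_genome)
    expect_setequal(seg$end - seg$start, lens)
    expect_true(all(seg$start >= 0))
    for (nm in unique(seg$chrom)) {
      s <- seg[seg$chrom == nm, ]
      expect_true(all(s$end <= toy_genome$length[toy_genome$chrom == nm]))
      if (nrow(s) > 1) {
        o <- order(s$start)
        expect_true(all(s$start[o][-1] >= s$end[o][-nrow(s)]))
      }
    }
  }
})

test_that("shuffle_segments respects exclusions and is seed-deterministic", {
  excl <- data.frame(chrom = c("c1", "c2"), start = c(0, 0),
                     end = c(100000, 49900))
  # only one 100 bp slot remains in the whole genome
  seg <- shuffle_segments(100, toy_genome, excl)
  expect_equal(seg$chrom, "c2")
  expect_equal(c(seg$start, seg$end), c(49900, 50000))
  # fixed seed -> identical placements
  set.seed(7); a <- shuffle_segments(c(500, 300), toy_genome)
  set.seed(7); b <- shuffle_segments(c(500, 300), toy_genome)
  expect_identical(a, b)
  # impossible placement errors out
  expect_error(shuffle_segments(200, toy_genome,
                                data.frame(chrom = c("c1", "c2"),
                                           start = c(0, 0),
                                           end = c(100000, 50000))),
               "space exhausted")
})

test_that("segment starts are uniform over the allowed space", {
  set.seed(62)
  genome1 <- data.frame(chrom = "c1", length = 1000)
  starts <- vapply(1:10000, function(k)
    shuffle_segments(100, genome1)$start, numeric(1))
  expect_true(all(starts >= 0 & starts <= 900))
  h <- table(cut(starts, breaks = seq(0, 901, length.out = 10),
                 include.lowest = TRUE))
  p <- stats::chisq.test(h)$p.value
  expect_gt(p, 0.001)
})

test_that("overlap_count and base_overlap follow half-open conventions", {
  segs <- data.frame(chrom = "c1", start = 0, end = 100)
  feats <- data.frame(chrom = "c1", start = c(50, 100, 200),
                      end = c(150, 120, 250))
  # touching at 100 is not an overlap
  expect_equal(overlap_count(segs, feats), 1L)
  expect_equal(base_overlap(segs, feats), 50)
  # nested features count once (union semantics)
  nested <- data.frame(chrom = "c1", start = c(10, 20), end = c(90, 60))
  expect_equal(base_overlap(segs, nested), 80)
  expect_equal(overlap_count(segs[0, ], feats), 0L)
})

test_that("overlap statistics agree with independent oracles", {
  set.seed(63)
  for (k in 1:30) {
    segs <- shuffle_segments(sample(200:2000, 4), toy_genome)
    nf <- sample(5:40, 1)
    feats <- data.frame(chrom = sample(toy_genome$chrom, nf, replace = TRUE),
                        start = sample(0:48000, nf))
    feats$end <- feats$start + sample(50:800, nf, replace = TRUE)
    expect_equal(overlap_count(segs, feats), oracle_overlap_count(segs, feats))
    expect_equal(base_overlap(segs, feats), oracle_base_overlap(segs, feats))
  }
})

test_that("permutation_test reaches its floor p on constructed enrichment", {
  set.seed(64)
  segs <- data.frame(chrom = "c1", start = c(10000, 40000),
                     end = c(12000, 42000))
  # plant features spanning nearly the full width of both observed segments,
  # so no random placement of the same two lengths can match the observed
  # count except by landing (almost) exactly on the observed segments
  feats <- data.frame(chrom = "c1",
                      start = c(seq(10050, 11900, by = 250),
                                seq(40050, 41900, by = 250)))
  feats$end <- feats$start + 60
  r <- permutation_test(segs, feats, toy_genome, statistic = "count",
                        n_perm = 999, seed = 65)
  expect_equal(r$direction, "enriched")
  expect_equal(r$p_enriched, 1 / 1000)
  expect_length(r$null_draws, 999L)
  # determinism under a fixed seed
  r2 <- permutation_test(segs, feats, toy_genome, statistic = "count",
                         n_perm = 999, seed = 65)
  expect_identical(r$null_draws, r2$null_draws)
  # p bounds
  expect_gte(r$p_value, 1 / 1000)
  expect_lte(max(r$p_enriched, r$p_depleted), 1)
})

test_that("adding a feature inside an observed segment never raises p", {
  set.seed(66)
  segs <- data.frame(chrom = "c1", start = 20000, end = 25000)
  feats <- data.frame(chrom = "c1", start = sample(0:90000, 15))
  feats$end <- feats$start + 300
  p0 <- permutation_test(segs, feats, toy_genome, statistic = "count",
                         n_perm = 199, seed = 5)$p_enriched
  feats2 <- rbind(feats, data.frame(chrom = "c1", start = 21000, end = 21300))
  p1 <- permutation_test(segs, feats2, toy_genome, statistic = "count",
                         n_perm = 199, seed = 5)$p_enriched
  expect_lte(p1, p0)
})

test_that("fills are enriched for planted repeats on the fixture", {
  fx <- default_fixture()
  res <- fixture_gapfill(fx, "clean")
  iv <- ledger_fill_intervals(res$ledger)
  segs <- data.frame(chrom = iv$chrom, start = iv$new_start, end = iv$new_end)
  # plant a repeat inside every second fill, a few outside
  set.seed(67)
  inside <- segs[seq(1, nrow(segs), 2), ]
  feats <- data.frame(chrom = inside$chrom, start = inside$start + 100,
                      end = inside$start + 400)
  genome <- data.frame(chrom = names(fx$deg$reference$seqs),
                       length = nchar(as.character(fx$deg$reference$seqs)))
  genome <- genome[fx$deg$reference$category == "chromosome", ]
  r <- permutation_test(segs, feats, genome, statistic = "count",
                        n_perm = 199, seed = 68)
  expect_equal(r$direction, "enriched")
  expect_lt(r$p_enriched, 0.01)
})
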