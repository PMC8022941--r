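# Truth-known synthetic fixtures.
#
# The generator builds a small "truth" genome (telomere cap + unique arms +
# centromeric monomer array per chromosome), degrades it into a draft-style
# reference (telomeres truncated, selected intervals masked to N-runs, some
# sequence pulled out as unplaced contigs), and emits the companion inputs
# every pipeline stage consumes: spanning donor contigs with precomputed
# alignments, barcoded linked-read alignments, telomere-bearing raw reads,
# centromere contigs, and optical-map coverage rows. Reads and contigs are
# error-free: the long-read inputs this emulates are assembled/polished
# sequence, so recovery can be asserted bit-exactly. Planted anomalies
# (translocated fill, non-linear homology donor, uncovered/wrong fill,
# mis-joined scaffold contig) let each validator stage prove it catches the
# failure mode it was designed for.

#' Simulation configuration
#'
#' @param seed RNG seed (mandatory).
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_len Chromosome length in bp (default 300000).
#' @param n_gaps Ordinary gaps per chromosome (default 5).
#' @param gap_len_range True gap-sequence length bounds (default 4600-6000 bp,
#'   large enough that fills pass a >4 kb collinearity filter when realigned).
#' @param gap_distortion Relative distortion of the recorded N-run length
#'   versus the true masked length (default 0.3, exercising the deviation
#'   tolerance; the true fill always has the true length).
#' @param telomere_len Telomere array length per end (default 3000 bp: 500
#'   hexamer copies, comfortably above a >50-occurrence threshold).
#' @param monomer_len Centromere monomer length (default 186 bp).
#' @param hor_period Number of distinct monomer variants in the
#'   higher-order-repeat block (default 3).
#' @param hor_copies Copies of the HOR block (default 8).
#' @param monomer_divergence Pairwise divergence between monomer variants
#'   (default 0.15).
#' @param n_chrun Unplaced-contig extractions per genome (default 2).
#' @param chrun_len_range Length bounds of extracted contigs (default
#'   5000-9000 bp).
#' @param donor_flank Donor anchor length on each gap flank (default 5000 bp,
#'   above the 4 kb alignment-length filter).
#' @param read_len,molecule_len,reads_per_molecule,depth Linked-read model:
#'   read length (150), molecule length (40 kb), reads per molecule (60),
#'   target mean depth (25x).
#' @param n_repeats,repeat_len_range,n_genes,gene_len_range Feature-track
#'   densities per chromosome.
#' @param anomalies Named counts: `translocated_fill`, `nonlinear_homology`,
#'   `uncovered_fill`, `misjoined_contig` (all default 0).
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed, n_chroms = 3L, chrom_len = 300000L, n_gaps = 5L,
                       gap_len_range = c(4600L, 6000L), gap_distortion = 0.3,
                       telomere_len = 3000L, monomer_len = 186L,
                       hor_period = 3L, hor_copies = 8L,
                       monomer_divergence = 0.15,
                       n_chrun = 2L, chrun_len_range = c(5000L, 9000L),
                       donor_flank = 5000L,
                       read_len = 150L, molecule_len = 40000L,
                       reads_per_molecule = 60L, depth = 25,
                       n_repeats = 30L, repeat_len_range = c(100L, 400L),
                       n_genes = 8L, gene_len_range = c(2000L, 6000L),
                       anomalies = list()) {
  fail_if(missing(seed) || is.null(seed), "sim_config: seed is mandatory")
  an <- list(translocated_fill = 0L, nonlinear_homology = 0L,
             uncovered_fill = 0L, misjoined_contig = 0L)
  an[names(anomalies)] <- anomalies
  fail_if(any(unlist(an) < 0), "anomaly counts must be >= 0")
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_len = chrom_len, n_gaps = n_gaps,
              gap_len_range = gap_len_range, gap_distortion = gap_distortion,
              telomere_len = telomere_len, monomer_len = monomer_len,
              hor_period = hor_period, hor_copies = hor_copies,
              monomer_divergence = monomer_divergence,
              n_chrun = n_chrun, chrun_len_range = chrun_len_range,
              donor_flank = donor_flank, read_len = read_len,
              molecule_len = molecule_len,
              reads_per_molecule = reads_per_molecule, depth = depth,
              n_repeats = n_repeats, repeat_len_range = repeat_len_range,
              n_genes = n_genes, gene_len_range = gene_len_range,
              anomalies = an)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, frac) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(v), max(1L, round(frac * length(v))))
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  v[idx] <- vapply(v[idx], function(b) {
    k <- sample.int(3L, 1L)
    substr(alt[[b]], k, k)
  }, character(1), USE.NAMES = FALSE)
  paste(v, collapse = "")
}

#' Simulate the truth genome
#'
#' Each chromosome is: left telomere (CCCTAA array) + unique arm +
#' centromeric HOR array + unique arm + right telomere (TTAGGG array).
#' Deterministic for a given config seed.
#'
#' @param config A [sim_config()].
#' @return list `truth` (an `assembly`), `tracks` (data.frames `telomeres`,
#'   `centromeres`, `repeats`, `genes`; truth coordinates), `cen_consensus`
#'   (the A variant), `monomer_variants` (character vector, length
#'   `hor_period`).
#' @export
simulate_truth_genome <- function(config) {
  set.seed(config$seed)
  tel <- config$telomere_len
  fail_if(tel %% 6L != 0L, "telomere_len must be a multiple of 6")
  variants <- character(config$hor_period)
  variants[1] <- random_dna(config$monomer_len)
  for (k in seq_len(config$hor_period)[-1])
    variants[k] <- mutate_dna(variants[1], config$monomer_divergence)
  cen_array <- strrep(paste(variants, collapse = ""), config$hor_copies)
  cen_len <- nchar(cen_array)
  seqs <- character(config$n_chroms)
  tel_l <- strrep("CCCTAA", tel / 6L)
  tel_r <- strrep("TTAGGG", tel / 6L)
  telomeres <- list(); centromeres <- list(); repeats <- list(); genes <- list()
  for (i in seq_len(config$n_chroms)) {
    nm <- paste0("chr", i)
    arm <- (config$chrom_len - 2L * tel - cen_len) %/% 2L
    arm2 <- config$chrom_len - 2L * tel - cen_len - arm
    seqs[i] <- paste0(tel_l, random_dna(arm), cen_array, random_dna(arm2), tel_r)
    cs <- tel + arm
    telomeres[[i]] <- data.frame(chrom = nm, start = c(0L, config$chrom_len - tel),
                                 end = c(tel, config$chrom_len), side = c("left", "right"))
    centromeres[[i]] <- data.frame(chrom = nm, start = cs, end = cs + cen_len)
    repeats[[i]] <- random_track(nm, config$n_repeats, config$repeat_len_range,
                                 tel, config$chrom_len - tel)
    genes[[i]] <- random_track(nm, config$n_genes, config$gene_len_range,
                               tel, config$chrom_len - tel)
  }
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  list(truth = assembly(seqs),
       tracks = list(telomeres = do.call(rbind, telomeres),
                     centromeres = do.call(rbind, centromeres),
                     repeats = do.call(rbind, repeats),
                     genes = do.call(rbind, genes)),
       cen_consensus = variants[1], monomer_variants = variants)
}

random_track <- function(chrom, n, len_range, lo, hi) {
  if (n == 0L) return(data.frame(chrom = character(), start = integer(),
                                 end = integer()))
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  starts <- sort(sample(lo:(hi - max(lens)), n))
  data.frame(chrom = chrom, start = starts, end = starts + lens)
}

#' Degrade the truth genome into a draft-style reference
#'
#' Truncates telomeres, masks the centromere array and `n_gaps` random
#' interior intervals per chromosome to N-runs (gap N-run lengths distorted
#' by up to `gap_distortion` relative to the truth), and extracts `n_chrun`
#' further intervals both as N-run gaps and as unplaced contig records named
#' `chrUn_*`. Returns the reference plus a truth ledger recording every
#' masking in both coordinate frames.
#'
#' @param sim Output of [simulate_truth_genome()].
#' @param config The same [sim_config()].
#' @return list `reference` (an `assembly`: chromosomes + chrUn records),
#'   `truth_ledger` (data.frame `chrom`, `type`, `ref_start`, `ref_end`,
#'   `truth_start`, `truth_end`, `true_len`, `contig`), `cen_gaps_ref`
#'   (centromere N-run intervals, reference coordinates), `tel_len`,
#'   `chrun_prior` (named chrom assignments of the extracted contigs).
#' @export
degrade_to_reference <- function(sim, config) {
  set.seed(config$seed + 1L)
  tel <- config$telomere_len
  flank <- config$donor_flank
  truth_seqs <- as.character(sim$truth$seqs)
  ref_seqs <- character(0)
  chrun_seqs <- character(0); chrun_prior <- character(0)
  ledger_rows <- list(); cen_rows <- list()
  chrun_counter <- 0L
  # masks keep a molecule length away from the scaffold ends so linked-read
  # coverage over every fill sits in its depth plateau
  edge <- config$molecule_len
  for (nm in names(truth_seqs)) {
    L <- nchar(truth_seqs[[nm]])
    cen <- sim$tracks$centromeres[sim$tracks$centromeres$chrom == nm, ]
    # choose non-overlapping mask intervals in the two arms, away from
    # telomeres, centromere and each other by at least one donor flank
    lens <- c(sample(config$gap_len_range[1]:config$gap_len_range[2],
                     config$n_gaps, replace = TRUE),
              sample(config$chrun_len_range[1]:config$chrun_len_range[2],
                     config$n_chrun, replace = TRUE))
    masks <- place_masks(lens,
                         arms = rbind(c(tel + flank + edge, cen$start - flank),
                                      c(cen$end + flank, L - tel - flank - edge)),
                         min_sep = 2L * flank + 500L)
    types <- c(rep("gap", config$n_gaps), rep("chrun", config$n_chrun))
    events <- data.frame(start = masks$start, end = masks$end, type = types)
    events <- rbind(events,
                    data.frame(start = cen$start, end = cen$end, type = "cen"))
    events <- events[order(events$start), , drop = FALSE]
    # assemble the reference chromosome left to right, recording masks
    pieces <- character(0)
    cursor <- tel                      # left telomere truncated
    ref_pos <- 0L
    for (j in seq_len(nrow(events))) {
      ev <- events[j, ]
      pre <- substr(truth_seqs[[nm]], cursor + 1L, ev$start)
      ref_pos <- ref_pos + nchar(pre)
      true_len <- ev$end - ev$start
      n_len <- if (ev$type == "gap" && config$gap_distortion > 0) {
        max(1L, round(true_len * stats::runif(1, 1 - config$gap_distortion,
                                              1 + config$gap_distortion)))
      } else true_len
      pieces <- c(pieces, pre, strrep("N", n_len))
      contig <- NA_character_
      if (ev$type == "chrun") {
        chrun_counter <- chrun_counter + 1L
        contig <- sprintf("chrUn_%03d", chrun_counter)
        chrun_seqs[[contig]] <- substr(truth_seqs[[nm]], ev$start + 1L, ev$end)
        chrun_prior[[contig]] <- nm
      }
      ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
        chrom = nm, type = ev$type, ref_start = ref_pos,
        ref_end = ref_pos + n_len, truth_start = ev$start,
        truth_end = ev$end, true_len = true_len, contig = contig,
        stringsAsFactors = FALSE)
      if (ev$type == "cen")
        cen_rows[[length(cen_rows) + 1L]] <- data.frame(
          chrom = nm, start = ref_pos, end = ref_pos + n_len)
      ref_pos <- ref_pos + n_len
      cursor <- ev$end
    }
    pieces <- c(pieces, substr(truth_seqs[[nm]], cursor + 1L, L - tel))
    ref_seqs[[nm]] <- paste(pieces, collapse = "")
  }
  list(reference = assembly(c(ref_seqs, chrun_seqs)),
       truth_ledger = do.call(rbind, ledger_rows),
       cen_gaps_ref = do.call(rbind, cen_rows),
       tel_len = tel, chrun_prior = chrun_prior)
}

# place non-overlapping mask intervals (one per requested length) inside the
# given arm intervals (matrix of [lo, hi)), separated by at least min_sep so
# donor flanks of adjacent masks never interleave. Constructive stars-and-
# bars placement within each arm; only the random arm assignment can fail
# (an overloaded arm), which is retried.
place_masks <- function(lens, arms, min_sep) {
  n <- length(lens)
  for (try in 1:100) {
    arm_pick <- sample(nrow(arms), n, replace = TRUE)
    starts <- numeric(n)
    ok <- TRUE
    for (a in seq_len(nrow(arms))) {
      idx <- which(arm_pick == a)
      if (length(idx) == 0L) next
      k <- length(idx)
      arm_len <- arms[a, 2] - arms[a, 1]
      need <- sum(lens[idx]) + (k - 1) * min_sep
      if (need > arm_len) { ok <- FALSE; break }
      u <- sort(stats::runif(k, 0, arm_len - need))
      ord <- sample(idx)
      offsets <- cumsum(c(0, lens[ord][-k] + min_sep))
      starts[ord] <- floor(arms[a, 1] + u + offsets)
    }
    if (ok) return(data.frame(start = starts, end = starts + lens))
  }
  stop("place_masks: could not place masks; loosen the configuration",
       call. = FALSE)
}

#' Simulate donor contigs and their reference alignments
#'
#' One donor per gap/chrUn mask: the truth sequence of the mask plus
#' `donor_flank` on each side. Half the donors (deterministically, by index
#' parity) are stored reverse-complemented to exercise minus-strand closure.
#' Alignment blocks are emitted from the known placement (identity 1), so no
#' external aligner is needed. Planted anomalies replace selected ordinary
#' gap donors:
#' \describe{
#'   \item{translocated_fill}{donor fill sequence taken from another
#'     chromosome (caught by the collinearity check).}
#'   \item{nonlinear_homology}{donor made of the two flank margins only, so
#'     its anchors imply a negative fill (caught by the shrinkage guard).}
#'   \item{uncovered_fill}{donor fill is random sequence absent from the
#'     truth genome (caught by linked-read support).}
#' }
#'
#' @param sim,deg,config Fixture pieces.
#' @return list `donors` (named character), `paf` (alignment blocks),
#'   `anomaly_table` (data.frame `kind`, `chrom`, `ref_start`, `ref_end`,
#'   `donor`).
#' @export
simulate_donors <- function(sim, deg, config) {
  set.seed(config$seed + 2L)
  flank <- config$donor_flank
  truth_seqs <- as.character(sim$truth$seqs)
  tl <- deg$truth_ledger[deg$truth_ledger$type %in% c("gap", "chrun"), ,
                         drop = FALSE]
  # assign anomalies to the first ordinary gaps of distinct chromosomes
  kinds <- c(rep("translocated_fill", config$anomalies$translocated_fill),
             rep("nonlinear_homology", config$anomalies$nonlinear_homology),
             rep("uncovered_fill", config$anomalies$uncovered_fill))
  gap_idx <- which(tl$type == "gap")
  fail_if(length(kinds) > length(gap_idx), "more anomalies than gaps")
  anomaly_of <- rep(NA_character_, nrow(tl))
  anomaly_of[gap_idx[seq_along(kinds)]] <- kinds
  donors <- character(0); paf_rows <- list(); anom_rows <- list()
  margin <- 800L                      # flank margin of the non-linear donor
  for (i in seq_len(nrow(tl))) {
    row <- tl[i, ]
    nm <- sprintf("donor_%s_%02d", row$chrom, i)
    ts <- row$truth_start; te <- row$truth_end
    fill_seq <- substr(truth_seqs[[row$chrom]], ts + 1L, te)
    kind <- anomaly_of[i]
    if (!is.na(kind) && kind == "translocated_fill") {
      other <- setdiff(names(truth_seqs), row$chrom)[1]
      src <- deg$tel_len + 2L * flank   # fixed interior locus of the other chrom
      fill_seq <- substr(truth_seqs[[other]], src + 1L, src + row$true_len)
    } else if (!is.na(kind) && kind == "uncovered_fill") {
      fill_seq <- random_dna(row$true_len)
    }
    if (!is.na(kind) && kind == "nonlinear_homology") {
      left_part <- substr(truth_seqs[[row$chrom]], ts - flank + 1L, ts - margin)
      right_part <- substr(truth_seqs[[row$chrom]], te + margin + 1L, te + flank)
      seq <- paste0(left_part, right_part)
      span <- flank - margin
      blocks <- data.frame(
        q_start = c(0L, span), q_end = c(span, 2L * span),
        t_start = c(row$ref_start - flank, row$ref_end + margin),
        t_end = c(row$ref_start - margin, row$ref_end + flank))
    } else {
      left_flank <- substr(truth_seqs[[row$chrom]], ts - flank + 1L, ts)
      right_flank <- substr(truth_seqs[[row$chrom]], te + 1L, te + flank)
      seq <- paste0(left_flank, fill_seq, right_flank)
      dlen <- nchar(seq)
      blocks <- data.frame(
        q_start = c(0L, dlen - flank), q_end = c(flank, dlen),
        t_start = c(row$ref_start - flank, row$ref_end),
        t_end = c(row$ref_start, row$ref_end + flank))
    }
    strand <- if (i %% 2L == 0L) "-" else "+"
    if (strand == "-") {
      dlen <- nchar(seq)
      seq <- revcomp_chr(seq)
      blocks[, c("q_start", "q_end")] <-
        data.frame(dlen - blocks$q_end, dlen - blocks$q_start)
    }
    donors[[nm]] <- seq
    w <- blocks$q_end - blocks$q_start
    paf_rows[[length(paf_rows) + 1L]] <- data.frame(
      query = nm, q_len = nchar(seq), q_start = blocks$q_start,
      q_end = blocks$q_end, strand = strand, target = row$chrom,
      t_len = NA_real_, t_start = blocks$t_start, t_end = blocks$t_end,
      matches = w, block_len = w, identity = 1, is_primary = TRUE,
      stringsAsFactors = FALSE)
    if (!is.na(kind))
      anom_rows[[length(anom_rows) + 1L]] <- data.frame(
        kind = kind, chrom = row$chrom, ref_start = row$ref_start,
        ref_end = row$ref_end, donor = nm, stringsAsFactors = FALSE)
  }
  list(donors = donors, paf = do.call(rbind, paf_rows),
       anomaly_table = if (length(anom_rows)) do.call(rbind, anom_rows)
       else data.frame(kind = character(), chrom = character(),
                       ref_start = numeric(), ref_end = numeric(),
                       donor = character()))
}

# expected coordinate of a truth position in the gap-filled (v5-like) frame:
# every mask is restored to its true length, telomeres stay truncated
truth_to_v5 <- function(pos, tel_len) pos - tel_len

#' Simulate barcoded linked-read alignments
#'
#' Molecules are placed uniformly over the chromosome interior (between the
#' truncated telomere boundaries); each contributes `reads_per_molecule`
#' error-free reads at uniform positions. Alignments are emitted in the
#' coordinates of the expected gap-filled assembly. Reads overlapping an
#' `uncovered_fill` anomaly interval are dropped (their sequence does not
#' exist in the patched assembly), which is what leaves such a fill without
#' linked-read support.
#'
#' @param sim,deg,config Fixture pieces.
#' @param anomaly_table From [simulate_donors()].
#' @return list `reads` (data.frame `read`, `barcode`, `chrom`, `start`,
#'   `end`), `n_total` (including dropped reads).
#' @export
simulate_linked_reads <- function(sim, deg, config, anomaly_table = NULL) {
  set.seed(config$seed + 3L)
  tel <- deg$tel_len
  rl <- config$read_len; ml <- config$molecule_len
  rpm <- config$reads_per_molecule
  drop_iv <- NULL
  if (!is.null(anomaly_table) && nrow(anomaly_table)) {
    bad <- anomaly_table[anomaly_table$kind == "uncovered_fill", , drop = FALSE]
    if (nrow(bad)) {
      tl <- deg$truth_ledger
      key <- match(paste(bad$chrom, bad$ref_start), paste(tl$chrom, tl$ref_start))
      drop_iv <- data.frame(chrom = bad$chrom,
                            start = truth_to_v5(tl$truth_start[key], tel),
                            end = truth_to_v5(tl$truth_end[key], tel))
    }
  }
  out <- list(); n_total <- 0L; bc_pool_n <- 0L
  for (nm in names(sim$truth$seqs)[sim$truth$category == "chromosome"]) {
    L <- nchar(as.character(sim$truth$seqs[[nm]]))
    interior <- c(tel, L - tel)
    span <- interior[2] - interior[1]
    n_mol <- ceiling(config$depth * span / (rpm * rl))
    bc_pool <- sprintf("BX%06d", bc_pool_n + seq_len(max(1L, n_mol %/% 2L)))
    bc_pool_n <- bc_pool_n + length(bc_pool)
    mol_start <- floor(stats::runif(n_mol, interior[1], interior[2] - ml))
    barcodes <- sample(bc_pool, n_mol, replace = TRUE)
    starts <- unlist(lapply(seq_len(n_mol), function(m)
      mol_start[m] + sort(sample.int(ml - rl, rpm))))
    df <- data.frame(read = sprintf("%s_rd%07d", nm, seq_along(starts)),
                     barcode = rep(barcodes, each = rpm), chrom = nm,
                     start = truth_to_v5(starts, tel),
                     end = truth_to_v5(starts, tel) + rl,
                     stringsAsFactors = FALSE)
    n_total <- n_total + nrow(df)
    if (!is.null(drop_iv)) {
      di <- drop_iv[drop_iv$chrom == nm, , drop = FALSE]
      for (k in seq_len(nrow(di)))
        df <- df[!(df$start < di$end[k] & df$end > di$start[k]), , drop = FALSE]
    }
    out[[nm]] <- df
  }
  list(reads = do.call(rbind, out) |> `rownames<-`(NULL), n_total = n_total)
}

#' Simulate telomere-bearing raw reads and their alignments
#'
#' One read per chromosome end: a unique anchor adjacent to the truncated
#' telomere plus the true telomeric tail. Right-end reads of even
#' chromosomes are stored reverse-complemented (minus-strand alignment).
#' Also emits one sub-threshold decoy read (exactly 50 motif copies, no
#' alignment) and one non-telomeric decoy.
#'
#' @param sim,deg,config Fixture pieces.
#' @param anchor_len Unique anchor length (default 12000, above the 10 kb
#'   uniqueness rule).
#' @return list `reads` (named character), `paf` (blocks in gap-filled
#'   coordinates), `expected` (data.frame `read`, `chrom`, `side`).
#' @export
simulate_telomere_reads <- function(sim, deg, config, anchor_len = 12000L) {
  set.seed(config$seed + 4L)
  tel <- deg$tel_len
  reads <- character(0); paf_rows <- list(); exp_rows <- list()
  chroms <- names(sim$truth$seqs)[sim$truth$category == "chromosome"]
  for (i in seq_along(chroms)) {
    nm <- chroms[i]
    seq_t <- as.character(sim$truth$seqs[[nm]])
    L <- nchar(seq_t); Lv5 <- L - 2L * tel
    for (side in c("left", "right")) {
      rd <- sprintf("telread_%s_%s", nm, side)
      if (side == "left") {
        r <- substr(seq_t, 1L, tel + anchor_len)
        q <- c(tel, tel + anchor_len); t <- c(0L, anchor_len)
      } else {
        r <- substr(seq_t, L - tel - anchor_len + 1L, L)
        q <- c(0L, anchor_len); t <- c(Lv5 - anchor_len, Lv5)
      }
      strand <- "+"
      if (side == "right" && i %% 2L == 0L) {  # exercise minus-strand merge
        rlen <- nchar(r)
        r <- revcomp_chr(r)
        q <- c(rlen - q[2], rlen - q[1])
        strand <- "-"
      }
      reads[[rd]] <- r
      paf_rows[[length(paf_rows) + 1L]] <- data.frame(
        query = rd, q_len = nchar(r), q_start = q[1], q_end = q[2],
        strand = strand, target = nm, t_len = Lv5, t_start = t[1],
        t_end = t[2], matches = anchor_len, block_len = anchor_len,
        identity = 1, is_primary = TRUE, stringsAsFactors = FALSE)
      exp_rows[[length(exp_rows) + 1L]] <- data.frame(read = rd, chrom = nm,
                                                      side = side)
    }
  }
  reads[["decoy_at_threshold"]] <- strrep("TTAGGG", 50L)  # exactly 50: rejected
  reads[["decoy_plain"]] <- random_dna(2000L)
  list(reads = reads, paf = do.call(rbind, paf_rows),
       expected = do.call(rbind, exp_rows))
}

#' Simulate centromere-bearing contigs and their alignments
#'
#' Chromosome 1 gets a spanning contig (periphery + full array + periphery),
#' chromosome 2 a left-side contig, chromosome 3 (and beyond) right-side
#' contigs. The array portion is not emitted as an alignment (it has no
#' match in the gapped reference); the unique peripheries are.
#'
#' @param sim,deg,config Fixture pieces.
#' @param periph Unique periphery length (default 15000).
#' @return list `contigs` (named character), `paf` (blocks, gap-filled
#'   coordinates), `cen_gaps_v5` (centromere gap intervals in the same
#'   frame), `expected` (data.frame `contig`, `chrom`, `side`).
#' @export
simulate_cen_contigs <- function(sim, deg, config, periph = 15000L) {
  tel <- deg$tel_len
  contigs <- character(0); paf_rows <- list(); exp_rows <- list()
  cen <- sim$tracks$centromeres
  cen_v5 <- data.frame(chrom = cen$chrom,
                       start = truth_to_v5(cen$start, tel),
                       end = truth_to_v5(cen$end, tel))
  chroms <- names(sim$truth$seqs)[sim$truth$category == "chromosome"]
  for (i in seq_along(chroms)) {
    nm <- chroms[i]
    seq_t <- as.character(sim$truth$seqs[[nm]])
    cc <- cen[cen$chrom == nm, ]
    side <- if (i == 1L) "spanning" else if (i %% 2L == 0L) "left_of_gap"
            else "right_of_gap"
    cg <- sprintf("cenctg_%s", nm)
    if (side == "spanning") {
      contigs[[cg]] <- substr(seq_t, cc$start - periph + 1L, cc$end + periph)
      qs <- c(0L, periph + (cc$end - cc$start))
      ts <- c(truth_to_v5(cc$start, tel) - periph, truth_to_v5(cc$end, tel))
    } else if (side == "left_of_gap") {
      contigs[[cg]] <- substr(seq_t, cc$start - periph + 1L,
                              cc$start + (cc$end - cc$start) %/% 2L)
      qs <- 0L
      ts <- truth_to_v5(cc$start, tel) - periph
    } else {
      contigs[[cg]] <- substr(seq_t, cc$start + (cc$end - cc$start) %/% 2L + 1L,
                              cc$end + periph)
      qs <- nchar(contigs[[cg]]) - periph
      ts <- truth_to_v5(cc$end, tel)
    }
    paf_rows[[length(paf_rows) + 1L]] <- data.frame(
      query = cg, q_len = nchar(contigs[[cg]]), q_start = qs,
      q_end = qs + periph, strand = "+", target = nm, t_len = NA_real_,
      t_start = ts, t_end = ts + periph, matches = periph,
      block_len = periph, identity = 1, is_primary = TRUE,
      stringsAsFactors = FALSE)
    exp_rows[[length(exp_rows) + 1L]] <- data.frame(contig = cg, chrom = nm,
                                                    side = side)
  }
  list(contigs = contigs, paf = do.call(rbind, paf_rows),
       cen_gaps_v5 = cen_v5, expected = do.call(rbind, exp_rows))
}

#' Simulate chrUn placement queries
#'
#' Builds the alignment inputs for unplaced-contig classification against
#' the gap-filled assembly: each extracted chrUn contig aligns fully inside
#' the fill that restored its sequence (`placed_in_gap`); one extra contig
#' copies pre-existing (never masked) chromosome sequence (`contained`);
#' one decoy contig is random sequence with no alignment (`unplaced`).
#'
#' @param sim,deg,config Fixture pieces.
#' @return list `contig_lens` (named), `seqs` (named character), `paf`
#'   (blocks in gap-filled coordinates), `prior` (named prior chromosome
#'   assignments, NA for the extras), `expected` (named expected verdicts).
#' @export
simulate_chrun_queries <- function(sim, deg, config) {
  set.seed(config$seed + 6L)
  tel <- deg$tel_len
  tl <- deg$truth_ledger[deg$truth_ledger$type == "chrun", , drop = FALSE]
  seqs <- character(0); paf_rows <- list(); prior <- character(0)
  expected <- character(0)
  for (i in seq_len(nrow(tl))) {
    nm <- tl$contig[i]
    seqs[[nm]] <- as.character(deg$reference$seqs[[nm]])
    len <- nchar(seqs[[nm]])
    v5s <- truth_to_v5(tl$truth_start[i], tel)
    paf_rows[[length(paf_rows) + 1L]] <- data.frame(
      query = nm, q_len = len, q_start = 0L, q_end = len, strand = "+",
      target = tl$chrom[i], t_len = NA_real_, t_start = v5s,
      t_end = v5s + len, matches = len, block_len = len, identity = 1,
      is_primary = TRUE, stringsAsFactors = FALSE)
    prior[[nm]] <- deg$chrun_prior[[nm]]
    expected[[nm]] <- "placed_in_gap"
  }
  # contained: pre-existing sequence just inside the left telomere boundary
  chrom1 <- names(sim$truth$seqs)[sim$truth$category == "chromosome"][1]
  cs <- tel + 1000L; clen <- 6000L
  seqs[["chrUn_contained"]] <- substr(as.character(sim$truth$seqs[[chrom1]]),
                                      cs + 1L, cs + clen)
  paf_rows[[length(paf_rows) + 1L]] <- data.frame(
    query = "chrUn_contained", q_len = clen, q_start = 0L, q_end = clen,
    strand = "+", target = chrom1, t_len = NA_real_,
    t_start = truth_to_v5(cs, tel), t_end = truth_to_v5(cs, tel) + clen,
    matches = clen, block_len = clen, identity = 1, is_primary = TRUE,
    stringsAsFactors = FALSE)
  prior[["chrUn_contained"]] <- NA_character_
  expected[["chrUn_contained"]] <- "contained"
  seqs[["chrUn_decoy"]] <- random_dna(6000L)
  prior[["chrUn_decoy"]] <- NA_character_
  expected[["chrUn_decoy"]] <- "unplaced"
  list(contig_lens = vapply(seqs, nchar, numeric(1)), seqs = seqs,
       paf = do.call(rbind, paf_rows), prior = prior, expected = expected)
}

#' Simulate optical-map coverage of the reference contigs
#'
#' Treats the inter-gap segments of each reference chromosome as scaffolded
#' contigs and emits one collinear optical alignment covering each, except
#' for `misjoined_contig` planted anomalies which get no coverage.
#'
#' @param deg,config Fixture pieces.
#' @return list `contig_table` (data.frame `chrom`, `name`, `start`, `end`),
#'   `optical` (data.frame as in [read_optical_tsv()]), `misjoined`
#'   (character vector of unsupported contig names).
#' @export
simulate_optical <- function(deg, config) {
  set.seed(config$seed + 5L)
  chroms <- names(deg$reference$seqs)[deg$reference$category == "chromosome"]
  gaps <- find_gaps(deg$reference)
  ct <- list(); opt <- list()
  for (nm in chroms) {
    g <- gaps[gaps$chrom == nm, , drop = FALSE]
    L <- nchar(as.character(deg$reference$seqs[[nm]]))
    s <- c(0L, g$end); e <- c(g$start, L)
    keep <- e > s
    ct[[nm]] <- data.frame(chrom = nm,
                           name = sprintf("%s_ctg%02d", nm, seq_len(sum(keep))),
                           start = s[keep], end = e[keep])
  }
  ct <- do.call(rbind, ct)
  mis <- character(0)
  if (config$anomalies$misjoined_contig > 0) {
    interior <- which(ct$start > 0)    # never pick a scaffold-leading contig
    mis <- ct$name[sample(interior, min(config$anomalies$misjoined_contig,
                                        length(interior)))]
  }
  covered <- ct[!ct$name %in% mis, , drop = FALSE]
  opt <- data.frame(optical_contig = sprintf("opt%03d", seq_len(nrow(covered))),
                    chrom = covered$chrom, start = covered$start,
                    end = covered$end, collinear = TRUE,
                    stringsAsFactors = FALSE)
  list(contig_table = ct, optical = opt, misjoined = mis)
}

#' Generate the complete fixture bundle
#'
#' Convenience wrapper running [simulate_truth_genome()],
#' [degrade_to_reference()], [simulate_donors()],
#' [simulate_linked_reads()], [simulate_telomere_reads()],
#' [simulate_cen_contigs()] and [simulate_optical()].
#'
#' @param config A [sim_config()].
#' @param with_reads Also simulate linked reads (the slowest part;
#'   default TRUE).
#' @return Named list with all fixture pieces.
#' @export
simulate_fixture <- function(config, with_reads = TRUE) {
  sim <- simulate_truth_genome(config)
  deg <- degrade_to_reference(sim, config)
  don <- simulate_donors(sim, deg, config)
  out <- list(config = config, sim = sim, deg = deg, donors = don,
              telomere = simulate_telomere_reads(sim, deg, config),
              centromere = simulate_cen_contigs(sim, deg, config),
              chrun = simulate_chrun_queries(sim, deg, config),
              optical = simulate_optical(deg, config))
  if (with_reads)
    out$linked <- simulate_linked_reads(sim, deg, config, don$anomaly_table)
  out
}
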