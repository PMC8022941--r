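---
title: "gapweaver: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gapweaver: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapweaver)
```

This vignette is the package's own account of what it computes, which
assumptions those computations rest on, and why the open design choices were
resolved the way they were. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The problem and the model

A draft reference assembly represents unresolved sequence inside chromosome
scaffolds as runs of `N`. Given a more contiguous donor assembly of the same
species, each gap can in principle be closed by a donor contig that aligns
to both gap flanks. The package models this as a pure interval-replacement
problem:

* A **gap** is a maximal N-run of length ≥ `min_run` (default 1) inside a
  chromosome-category sequence. Unplaced sequences are never scanned; runs
  touching scaffold ends still count. `min_run` is configurable because no
  principled minimum exists — a single N is still unresolved sequence.
* A **fill** replaces exactly the gap interval. Donor anchors rarely abut
  the gap edge exactly, so the donor coordinates of the gap boundaries are
  obtained by collinear extrapolation from the nearest anchor edge: for a
  plus-strand left anchor ending `m` bp before the gap, the fill starts `m`
  bp after the anchor's donor end (minus strand mirrored). Restricting the
  replaced interval to the N-run gives an unconditional safety property,
  asserted on every run: *filled bases never overwrite non-N reference
  bases*.

### The deviation tolerance

Draft gap lengths are size estimates, not measurements, so the fill length
is allowed to deviate: a closure is accepted when

\[ \frac{|L_\text{fill} - L_\text{gap}|}{\max(L_\text{gap}, 1)} \le a, \]

with `a = 1` by default, i.e. the fill may be up to twice the recorded gap
length, or arbitrarily short. The ratio interpretation is one of several
readings of a scalar "allowed deviation" parameter; it is exposed as a plain
config knob so stricter curation (`a = 0.25`, say) is one argument away. The
`max(·, 1)` guard makes zero-length recorded gaps well-defined.

### The shrinkage guard

A donor carrying a short out-of-place homology can anchor on both flanks
while its anchors' gap-boundary images *cross* on the donor, implying a
negative fill length. Splicing such a donor would ligate the two gap ends
and delete flanking sequence. With fills confined to the gap interval, the
two formulations coincide exactly:

> fill length < 0  ⇔  new chromosome length < old length − gap length,

and `shrinkage_guard()` rejects precisely these proposals
(`rejected_shrinkage`). Anchors whose donor intervals are *completely*
reversed are rejected earlier (`rejected_order`) — that pattern indicates
wholesale non-linear homology rather than a crossing boundary, and no fill
coordinate can even be defined. `rejected_order` is an extra outcome beyond
the basic closed/partial/unfilled/rejected set; reports count it with the
rejections.

### Partial fills

A gap with a usable anchor on only one flank receives the donor overhang
from that side, capped at min(overhang, gap length, `max_ext`). The cap at
the gap length means partial fills never change scaffold length — growth of
a scaffold without a second anchor would be unverifiable.

### Competing donors

When several donors span one gap, the pair with the highest summed anchor
identity wins; ties fall back to longest summed anchor span; an exact tie is
refused with a warning (ambiguous evidence should not silently pick a
winner). One fill per gap, one pass — iterative re-filling rounds would
compound errors without new evidence.

## Alignment thresholds

All thresholds follow the conventions of the gap-closing literature and are
arguments everywhere they are used:

| parameter | default | used by | note |
|---|---|---|---|
| collinearity identity | > 0.98 (strict) | anchor filter, fill validation | identity = PAF matches / block length |
| collinearity span | > 4 kb (strict) | same | target-interval span |
| placement query fraction | ≥ 0.90 (inclusive) | chrUn placement | aligned query bases per locus |
| placement mismatch | ≤ 0.02 (inclusive) | same | (aligned − matches) / aligned, a BLAT-style dialect |
| unique anchor | > 10 kb (strict) | telomere & centromere assignment | bases covered by exactly one primary block |
| telomere motif count | > 50 (strict) | read selection | non-overlapping exact TTAGGG / CCCTAA |
| optical support | ≥ 0.50 (inclusive) | contig pruning | covered fraction of contig length |
| anchor flank window | 1 kb | gap anchoring | donor anchor must end/start within this window of a gap edge |

Strict versus inclusive follows each rule's phrasing ("greater than" vs "at
least"/"or less"). Two rules deserve comment:

* **The optical support rule** is stated in its source as a double negative
  ("not supported if less than 50% of its length did not overlap") whose
  literal reading is self-contradictory; the package implements the only
  self-consistent intent — supported ⇔ ≥ 50% of the contig overlaps optical
  alignments, inclusive at exactly 0.5.
* **Uniqueness** is defined as coverage multiplicity 1 among primary
  alignments. No mapping-quality threshold is layered on top, since the
  upstream convention is simply "primary alignments only"; MAPQ semantics
  vary by aligner and would smuggle in a second, undocumented filter.
* **Placement loci**: split alignments on one target are summed into one
  locus when separated by ≤ 50 kb, then the 90%/2% rule is applied per
  locus. Summation (rather than requiring one monolithic alignment) matches
  how BLAT-style hits fragment around small indels.

## Linked-read validation

Barcoded reads are clustered into molecules by single linkage within a
barcode and chromosome, splitting when adjacent reads are > 50 kb apart —
the size-selection bound of the library preparation this emulates, so reads
further apart cannot come from one molecule. A closed gap is **supported**
when

1. every base of the fill ± `flank` (default 100 bp) has depth ≥
   `depth_threshold` (default 1), and
2. at least one molecule has reads on both flanks.

Condition 2 exists so a single mis-mapped read inside a wrong fill cannot
rescue it; molecule-level spanning is the actual long-range evidence.
Defaults are deliberately permissive (depth 1) because the claim being
tested is "sequence exists here", not "coverage is uniform"; both knobs are
exposed. Unsupported gaps are reported, never reverted — a small fraction of
unsupported closures may be genuine structural variation between the
populations providing the reference and the reads, and silently undoing
them would hide that signal. Support is monotone in `depth_threshold` by
construction (a property test asserts it).

## Telomeres and centromeres

Telomeric reads are found by exact non-overlapping motif counting
(case-insensitive, no degenerate bases — the motif is invariant and fuzzy
matching would admit low-complexity false positives). Assignment demands
> 10 kb of uniquely aligning sequence within `end_window` (default 50 kb) of
a terminus; a read anchoring at two ends is ambiguous and dropped. Merging
appends only the unaligned overhang — anchor overlap is never duplicated,
and existing bases are never modified; each chromosome end takes at most one
extension (longest overhang wins).

Centromeric monomers are located by approximate matching of the consensus
monomer on both strands with up to (1 − `min_identity`) errors (default
`min_identity` 0.75 — satellite monomers diverge fast, and the reported
per-hit identity lets users re-filter). Hits are made non-overlapping
greedily left to right. The HOR period maximises the lagged mean identity
score(p) = mean identity(monomer i, monomer i+p), p ranging to n/3 so every
candidate period is observed at least three times; a period is accepted only
when it beats score(1) by `margin` (default 0.02, i.e. 2 identity points).
A period-1 outcome is flagged *confident* only when adjacent copies are
near-identical (score(1) ≥ `tandem_identity`, default 0.95): a shuffled
array of divergent monomers has no period, and its period-1 call is
reported with `confident = FALSE` rather than dressed up as a tandem. For
short arrays the lag means are noisy (a lag-p score averages only n − p
pairs), so the test suite's randomized-order control uses a 60-monomer
array and a 5-point margin, where the no-period call is far outside
sampling noise.

## Enrichment permutations

The observed segments are the ledger's fill intervals — the actual
length multiset is shuffled, rather than one aggregate block, matching how
interval shufflers operate and conserving the length distribution exactly
(a test asserts the multiset is conserved in every null draw). Placements
are uniform over all genome positions where the segment fits inside one
chromosome without touching an excluded interval or a previously placed
segment; self-overlap is disallowed (the conservative choice where the
convention is unstated). The empirical p-value uses the add-one correction,
so p is never 0 and the floor is 1/(n_perm + 1); both tails are reported.
Chromosome-restricted shuffling (no unplaced sequence) keeps the null on
comparable territory. Type-I calibration at α = 0.05 is asserted over 200
null simulations with n_perm = 999.

## The synthetic stated world

The default `sim_config()` is a desk-scale genome meant to exercise every
code path in seconds, not to mimic a real karyotype: 3 chromosomes × 300 kb;
3 kb telomere arrays per end (500 hexamer copies — comfortably above the
>50-copy selection threshold); a centromeric array of 8 copies of a 3-monomer
HOR block (186 bp monomers, 15% divergence between variants); 5 ordinary
gaps (true length 4.6–6 kb, so fills exceed the 4 kb re-alignment filter)
plus 2 chrUn extractions (5–9 kb) per chromosome; donors with 5 kb anchors;
linked reads at 25× from 40 kb molecules (60 × 150 bp reads each). Gap
N-run lengths are distorted by up to ±30% relative to the truth to exercise
the deviation rule. Masks keep one molecule length away from scaffold ends
so every fill sits in the linked-read depth plateau — nearer the ends,
molecule starts are truncated and depth-1 dropouts would be sampling
artefacts, not evidence.

Reads and contigs are error-free: the inputs this emulates are assembled,
polished sequence, and exactness is what lets the suite assert bit-identical
recovery. Consequently a green fixture test establishes correctness of the
*mechanics* (anchoring arithmetic, strand handling, coordinate bookkeeping,
guard logic) — it says nothing about robustness to sequencing error,
heterozygosity, or repeat-induced mis-anchoring, which real data would add.
Half the donors are stored reverse-complemented so minus-strand closure is
always exercised.

Planted anomalies are constructed, not simulated: the translocated donor
carries its fill from another chromosome (same length, so it closes and
only the collinearity check can catch it); the non-linear donor consists of
the two flank margins only, so its anchor images cross and the shrinkage
guard must fire; the uncovered donor's fill is random sequence, so linked
reads — emitted from the truth genome — are dropped over it and only the
linked-read validator can catch it. Linked-read alignments over the
translocated fill are emitted normally, reflecting that its sequence exists
elsewhere in the genome and would attract alignments; the anomaly is
therefore invisible to the depth test and caught exactly once, by the
collinearity check.

## Numerical and degenerate-input decisions

* Coordinates are 0-based half-open throughout; IRanges' 1-based closed
  convention and XMAP's 1-based positions are converted at the boundary.
* Non-ACGTN symbols are replaced by N at load with a warning counting the
  replacements; case is folded to upper.
* A zero-length recorded gap compares deviation against max(gap, 1).
* Ledger edits must be non-overlapping and within bounds; abutting edits
  are legal. Overlap is rejected at construction with a coordinate-conflict
  error rather than at application time.
* `assignment_concordance` on an empty eligible set returns an explicit
  undefined flag, never 0 — "no evidence" and "0% concordant" are different
  findings.
* Empty alignment streams, empty read sets and donor-less gaps are ordinary
  inputs (empty results / `unfilled`), not errors.
* `parse_paf` skips malformed lines with a counted warning; a missing
  `tp:A` tag means primary, matching the common aligner convention.

## Known limitations

* The gap filler is a faithful implementation of the published *behaviour*
  of flank-anchored closing (span completely, or partially from either
  end), not a bug-for-bug clone of any specific tool's internal seeding and
  trimming heuristics.
* Collinear extrapolation across the anchor-to-gap margin assumes no indel
  within that margin (≤ the 1 kb flank window). On error-free donors this
  is exact; on noisy donors it can misplace fill boundaries by the size of
  an unmodelled indel.
* `unique_anchor_span` measures uniqueness among the alignments provided;
  if a caller supplies a pre-filtered subset, uniqueness is relative to
  that subset.
* The centromere monomer scan is approximate pattern matching, not a
  profile/HMM search; highly diverged monomer families below
  `min_identity` are invisible to it.
* The enrichment null treats chromosomes as homogeneous; it does not
  stratify by GC, repeat density or distance to features, which a more
  conservative genomic null might.
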