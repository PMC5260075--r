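---
title: "Methods: trie-based barcode-seq mapping and screen statistics"
author: "bartrie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trie-based barcode-seq mapping and screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartrie)
```

# The problem

A pooled screen tags each construct — an shRNA, an sgRNA, or a yeast
deletion cassette — with a short artificial DNA barcode, and the screen
readout is the count of each barcode in sequencing data. The read layout
is `[MID] [primer] barcode [...]`: an optional multiplex ID identifying
the sample within a lane, an optional universal primer, and the barcode
itself, usually followed by downstream construct sequence the mapper must
ignore. Single-tag libraries carry one barcode per construct; pair-tag
yeast deletion collections carry two (`UP` and `DN`) flanking the same
cassette, whose counts should agree.

Three error processes complicate counting. Sequencing and PCR introduce
mismatches and indels in otherwise-correct barcodes. Library synthesis,
strain maintenance and genomic integration can corrupt the *barcode
itself*, so the pool sequence differs from the design ("erroneous
barcodes") and exact matching silently loses those constructs. And short
barcodes designed under biological constraints often sit within one edit
of each other, so a single error can transfer a read between genes
(off-target counts). The package addresses all three: imperfect matching
with explicit ambiguity accounting, erroneous-barcode detection, and
library-wide similarity QC.

# Mapping

## Matching semantics

The library's barcode sequences are indexed in a trie (prefix tree);
identical sequences under different ids share one terminal. A search for
read segment $s$ with budget $e$ returns every library sequence $b$ with

$$\min_{k} \; d(b,\, s_{1..k}) \le e,$$

where $d$ is unit-cost Levenshtein distance: the barcode must match a
*prefix* of the segment, and segment bases beyond the matched barcode are
free. This "dynamic sequence length" rule is what permits libraries of
mixed barcode lengths and reads that run past the barcode into construct
sequence. The converse also holds: a barcode may hang over the end of a
short read, paying one deletion per overhanging base, provided the total
stays within budget — a deliberate decision for truncated final reads.
Insertions and deletions are counted relative to the library sequence; a
non-ACGT read base (such as `N`) matches nothing and always costs a
mismatch.

The search walks the trie depth-first carrying one dynamic-programming
row per depth, pruning a subtree as soon as the row minimum exceeds the
budget; the batch mapper short-circuits reads whose segment starts with a
verbatim library sequence, since a 0-error hit can only be tied by
another exact hit. The contract, not the mechanism, is normative: the
test suite holds the trie to exact equivalence with a naive
per-sequence prefix-tolerant distance scan over hundreds of random
libraries, and to monotonicity of hit sets in the budget. The supported
budget is capped at 5; screens in practice use at most 2, and the cap
bounds both recursion and the explored neighbourhood.

Per barcode the minimal error count is reported. Among equal-cost
alignments the one with fewest indels, then fewest insertions, then the
longest consumed span is kept — an arbitrary but deterministic order, so
identical inputs always produce byte-identical outputs.

## Primer shifts, MIDs, ambiguity

When the library declares a universal primer, each read is first aligned
primer-versus-read-prefix with the same prefix-tolerant distance
(default budget 2). The alignment's consumed read length marks where the
barcode starts, so indels in the primer shift the barcode start by their
net balance. For this alignment ties at minimal cost are resolved toward
the *longest* consumed span: a read with an inserted base inside the
primer must have the insertion claimed by the primer, or the shift is
lost. A user-supplied fixed barcode start skips primer matching entirely.

MID demultiplexing assigns each read to the unique MID matching its 5'
prefix; the default budget is 0 because MIDs are short and a miscalled
index costs a whole sample. With nested or variable-length MIDs
(real index sets run 9–17 nt) the longest exact match wins; residual ties
go to an `unassigned` bin, and assigned reads have the matched prefix
stripped. The bins always partition the input counts.

A read whose minimal-error hit set has exactly one member is assigned;
two or more minimal hits make it *ambiguous*, counted but never
attributed — uniquely mapped reads only. Per barcode the mapper splits
counts into `exact` (0 errors) and `mutated` (≥ 1), and records the read
segment of every mutated unique hit in a variants table. The
conservation identity `mapped + ambiguous + unmapped (+ filtered) =
input` is enforced by the result class's validity method.

# Library QC

## Static and dynamic similarity

Two comparison modes quantify barcode similarity. *Static* is the full
global edit distance with all end gaps charged. *Dynamic* stops charging
once the reference sequence has ended — exactly the mapper's matching
rule — and is therefore directional; dynamic never exceeds static. For
the pair report the minimum over both directions is used, since a
collision in either direction is a collision; mapping itself always uses
the library sequence as reference. The canonical four-base example:
`AGCT` vs `ACTA` is distance 2 statically (alignment `AGCT-` /
`A-CTA`, the trailing gap charged) but 1 dynamically (the trailing base
falls after `AGCT` has finished). The report labels each close pair
intra- (same gene) or inter-gene and summarizes, per mode, how many
barcodes have at least one close partner — inter-gene pairs are the
off-target risk.

## Erroneous barcodes

A barcode whose pool sequence differs from its design shows a
characteristic signature under imperfect matching: almost no exact-match
reads, a large mutated count, and that mutated count concentrated in a
*single* variant sequence (the true pool sequence). Sequencing/PCR noise
has the opposite profile: a large exact count with a small mutated count
spread over many variants. The decision rule flags a barcode when all
three hold:

1. total mapped count ≥ `minImperfectCount` (default 100) — enough
   evidence;
2. `(mutated + 1) / (exact + 1)` ≥ `ratioThreshold` (default 10) — the
   pseudocounts keep the ratio finite at zero exact counts;
3. one variant holds more than `dominantFraction` (default 0.5) of the
   mutated reads.

The numeric thresholds are this package's own calibration of a
qualitative criterion; they are exposed as arguments, and the synthetic
pools (injected mutants at ≥ 10-fold excess) are detected at 100%
sensitivity with zero false positives at these defaults. Flagged
barcodes can be *removed* (counts moved to a `filtered` tally so
conservation still balances — appropriate for RNAi, where a mutated
construct no longer silences its target) or *replaced* (the dominant
variant becomes the accepted sequence, via `applyFixes()` for
re-mapping; a replacement colliding with an existing barcode is an
error).

# Sample QC

Per sample: mapped count and percentage, ambiguous (multi-mapping) and
unmapped tallies, and per-barcode count ratios (count / mapped total,
summing to 1) with their quartiles. For pair-tag data, UP and DN counts
of each gene are correlated on the log2(count + 1) scale — Pearson by
default, Spearman as an option since no estimator is canonical here —
and genes missing one tag are excluded with a warning. Low UP/DN
correlation indicates sample degradation or library problems, because
both tags measure the same strain.

# Case/control statistics

## Normalization and filtering

Counts are made positive with a pseudocount and scaled to within-sample
ratios,

$$r_{bs} = \frac{c_{bs} + 1}{\sum_{b'} (c_{b's} + 1)},$$

then averaged over replicates within each condition. The low-count
filter removes barcodes whose *raw* replicate-mean counts are below the
threshold (default 100) in **both** conditions — depletion to zero in
the case arm is signal, not noise, so one adequately measured side
suffices. The filter deliberately operates on counts, not ratios: "low
counts" is a statement about measurement depth.

## Scores, clustering, ranking

Per unfiltered barcode, $\mathrm{fc} = \log_2(\bar r_{case} /
\bar r_{control})$ and $z = (\mathrm{fc} - \overline{\mathrm{fc}}) / s$,
with $s$ the sample standard deviation over all unfiltered barcodes
(population sd available as an option). The fc statistic is the standard
pseudocounted log-ratio of pooled-screen analysis; swapping condition
labels negates every score, and per-sample scaling leaves scores
invariant up to the vanishing pseudocount perturbation. Fewer than two
unfiltered barcodes, or zero spread, are errors rather than silent NAs.

Within each gene, barcodes are clustered by one-dimensional
single-linkage on z: sort, cut where the gap between neighbours exceeds
`gap` (default 1 z-unit) — the simplest scheme consistent with grouping
concordant barcodes. A cluster with fewer members than a quarter of the
gene's unfiltered barcodes (strict inequality, verified by exhaustive
enumeration over all cluster compositions of group sizes 1–12) is
discarded as off-target signal and its members flagged. Kept clusters
get `cluster_fc` (mean member fc) standardized into `cluster_z`
*across genes* — within-gene standardization would erase the between-gene
differences the ranking exists to expose — and are ranked ascending
(most depleted first, ties by gene id). Pair-tag UP/DN counts are summed
per strain before scoring (mean available as an option).

Time-course designs get per-time-point fc-scores against that time
point's own controls, in long format for heat-map rendering; time points
missing a condition are skipped with a warning, and fewer than two
usable time points is an error.

# Synthetic data: the stated world

The generator exists so every claim above is testable against ground
truth without external downloads. Its defaults describe one fixed,
realistic world: 100 genes × 5 barcodes of 20 nt, designed at pairwise
static distance ≥ 3 (rejection sampling, as a designed library should
be); an 18-nt universal primer; log-normal barcode abundances
(meanlog = log 400, sdlog = 0.5 — the right-skewed depth profile pooled
libraries show); per-base substitution 0.5% and indels 0.05% each
(Illumina-scale); 2% of reads gaining one extra 5' base (shift); four
random 3' pad bases so reads overrun the barcode; two replicates;
depletion effects of log2 fc −2 where requested. Per-read error counts
are drawn binomially per read — equivalent to independent per-base
trials, and checked against the binomial law by a goodness-of-fit test.
Erroneous barcodes are modeled as *pool-level* substitutions: every read
of an injected barcode carries the mutant sequence, because the physical
construct, not the read, is wrong. Counts-only screens draw Poisson
observations around the abundance model, with case means scaled by
$2^{\mathrm{effect}}$ (compounded per time point in time-course mode).

What the generator does not emulate: PCR jackpotting and amplification
bias, quality-score structure, chimeras, and contamination. A green test
therefore establishes correctness of the algorithms under the stated
error model, not robustness to every artifact of real libraries.
Seeding is mandatory and outputs are byte-identical under a fixed seed.

# Numerical and design decisions

- **Unit edit costs.** Mismatch, insertion and deletion all cost 1; no
  weighting scheme is canonical for barcode data.
- **Tie-breaks.** Barcode hits: fewest indels, then fewest insertions,
  then longest consumed span. Primer/MID alignment: longest consumed
  span at minimal cost (see above — shift correction depends on it).
- **Budget cap 5** keeps the trie recursion and neighbourhood bounded.
- **Sample sd** (n−1) for z-scores, configurable; with hundreds of
  barcodes the difference is cosmetic, but the convention is stated.
- **Strict quarter rule**: a cluster is removed iff members < total/4;
  a singleton in a 4-barcode gene (1 < 1 false) survives.
- **Cluster z across genes**, not within — within-gene standardization
  would make every gene look alike.
- **UP/DN merge by sum** before scoring; the mean option changes no
  ranking, only scale.
- **MID budget 0 by default**; fuzzy MID matching is available but
  collisions between samples are costlier than discarded reads.
- **Degenerate inputs**: empty read files are valid (empty seqmap);
  all-zero samples normalize to uniform ratios with a warning; fewer
  than two scorable barcodes, zero fc spread, or a single usable time
  point are errors.

# Limitations

No multi-condition comparisons beyond case/control, no p-value or FDR
machinery (the scores are ranking statistics, not calibrated tests), no
reverse-complement auto-detection, no per-base quality use, and no
paired-end merging. The erroneous-barcode thresholds are a documented
stand-in calibrated on synthetic pools; real libraries may need
adjustment through the exposed arguments.
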