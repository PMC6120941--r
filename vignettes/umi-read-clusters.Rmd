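---
title: "Detecting and collapsing UMI-read clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and collapsing UMI-read clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umishift)
```

## The artefact

A unique molecular identifier (UMI) is a random oligomer ligated to each
input molecule before amplification, so that all PCR copies of one molecule
carry the same tag. The standard deduplication assumption is that reads
sharing a UMI and a mapping coordinate are copies of one molecule, while
reads at different coordinates are different molecules. In UMI-tagged
RNA-Seq libraries that assumption fails in a specific, structured way:
reads sharing a UMI frequently map to a *run* of closely spaced
coordinates — a modal position holding most of the reads, with diminishing
numbers one or a few base pairs up- and downstream, forming a bell-shaped
pattern. We call such a run a **UMI-read cluster**; its **size** is the
number of distinct adjacent coordinates, and the **mapping shift** of a
read is the offset between its coordinate and the cluster's modal
coordinate. When every spacing between adjacent coordinates equals *n* bp
the cluster has shifts of **strictly n** — the uniform spacings (1, 2, 3 bp)
are what implicates repeat-stabilized PCR stutter, which in short-tandem-
repeat genotyping produces products differing by whole repeat units.

If each (UMI, coordinate) pair is counted as a distinct molecule, every
cluster of size *k* inflates the gene's molecule count *k*-fold for that
template. The correction is to **collapse** each cluster into a single
observation of its UMI at the modal coordinate.

## The procedure

Given uniquely aligning reads (SAM records with `NH:i:1`, UMI carried in
the QNAME) the pipeline is:

1. **Per-coordinate UMI merging.** At each (reference, strand, coordinate),
   UMIs within Levenshtein distance 1 of each other are treated as the same
   tag mutated by PCR or sequencing error. The "distance ≤ 1" relation is
   not transitive, so a deterministic greedy policy is required: UMIs are
   visited in descending read count, ties broken lexicographically; each
   joins the earliest-founded representative within distance 1, otherwise
   it founds a new group. Abundance-first greedy assignment mirrors
   established UMI error correctors; the representative is therefore always
   the most abundant member.
2. **Coordinate chaining.** For each (reference, strand, representative
   UMI), sorted coordinates are chained single-linkage: a new cluster
   starts when the gap to the previous coordinate exceeds `max_gap`
   (default 3 bp). A cluster may span more than `max_gap` in total, which
   is how large clusters (dozens of adjacent positions) arise under a 3 bp
   rule. Across positions, UMI identity is exact string equality of
   representatives — the Levenshtein tolerance applies only within one
   coordinate, where co-occurrence makes common origin likely.
3. **Collapsing.** Each cluster becomes one molecule observation at its
   modal coordinate (ties in per-coordinate counts take the leftmost
   coordinate — deterministic and order-independent).
4. **Gene counting.** Collapsed and uncollapsed observations are projected
   onto GFF3 `gene` features (single-base sites, interval overlap with
   strand ignored, as in a plain `bedtools intersect`). The per-gene ratio
   uncollapsed/collapsed is the factor by which the artefact inflates the
   apparent expression of that gene.

### Parameters that matter

* `max_gap` (bp, default 3): the largest spacing joined into one cluster.
  Spacings between coordinates sharing a UMI are overwhelmingly 1–3 bp,
  with frequencies dropping off rapidly beyond, so raising the threshold
  past 3 changes little; it is configurable so that sensitivity can be
  explored. `max_gap = 0` degenerates exactly to per-coordinate UMI
  counting.
* `min_mean_phred` (default 30): reads whose UMI substring has mean Phred
  quality below 30 are discarded before alignment. The UMI is the one part
  of the read where an error silently splits or merges molecules, so it is
  held to a higher standard than the biological sequence. The filter is
  applied uniformly to all layouts by default (it can be disabled), since
  protocols differ only in where the UMI is carried.
* Levenshtein radius 1 for same-coordinate merging: fixed, matching the
  error regime of a single PCR/sequencing mutation in a short tag.
* Strand: positions are keyed by (reference, strand, coordinate) by
  default, because sense and antisense reads at one coordinate are
  distinct molecules; `ignore_strand = TRUE` reproduces a strand-blind
  reading, since a SAM-line-oriented pipeline that keys on POS alone never
  consults the strand flag. The coordinate is the leftmost POS for both
  strands — appropriate for end-to-end alignments, but different from UMI
  tools that use the 5' end of reverse-strand reads; with soft-clipping
  absent (end-to-end alignment) POS is used as-is.

## Sequence complexity of modal reads

Low-complexity templates (homopolymers, short tandem repeats) are the
natural substrate for stutter. Two per-read statistics quantify this, both
computed only for the **modal read** of each cluster (one record per
cluster, not per read; the modal read is the most frequent sequence at the
modal coordinate, ties lexicographic):

* **Shannon entropy** over base fractions,
  \(H = -\sum_{x \in \{G,A,T,C\}} p(x)\,\log_2 p(x)\), with
  \(0 \log_2 0 = 0\). Homopolymers score 0, perfect dinucleotide repeats
  1, uniform composition 2. (The conventional minus sign is required for
  these reference values to hold.)
* **Mutual information** between odd and even positions: the string is
  made even by dropping its first character, split into consecutive
  non-overlapping 2-mers \((x, y)\), and
  \(I = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)\,p(y)}\), where
  \(p(x,y)\) is the fraction of 2-mers and the marginals are the base
  fractions of the whole evened string. The whole-string marginals are
  what make a perfect dinucleotide repeat score 2.0 — e.g. for
  `"AT"` repeated, \(p(A,T) = 1\), \(p(A) = p(T) = 1/2\), so
  \(I = \log_2 4 = 2\); per-position marginals would give 0 instead. For a
  worked small case, `"AAAT"` has pairs {AA, AT}, marginals
  \(p(A) = 3/4, p(T) = 1/4\), giving
  \(0.5\log_2(0.5/0.5625) + 0.5\log_2(0.5/0.1875) \approx 0.6226\).

Note that for uniformly random reads both plug-in statistics are biased —
the entropy estimator falls below 2 bits and the MI estimator is positive
even under independence, by the usual finite-sample arguments — so
averages quoted for "random" reads depend on the sampling procedure.
Only the exact repeat/homopolymer values serve as reference values here.

The trend across cluster sizes is tested with a classical one-way
fixed-effects ANOVA (`stats::aov`) with cluster size as the factor,
separately for each metric. Size groups with fewer than 2 records are
dropped (their within-group variance is undefined); if the within-group
mean square vanishes while means differ, F is reported as infinite with
p = 0 rather than a floating-point overflow.

## The simulator

`simulate_library()` generates the study conditions end to end: a random
reference chromosome with evenly spaced genes, molecules tagged with
uniform random UMIs, and reads whose mapping starts carry a stutter offset.
Stutter is modelled at the mapped-start level — each read's lineage through
`pcr_cycles` amplification cycles accumulates, on repeat-bearing templates
only, a ±1-repeat-unit step with per-cycle probability `stutter_prob` (a
lazy random walk). The walk's net displacement naturally produces a modal
position with diminishing flanks, so the bell shape emerges from the
mechanism rather than being drawn directly. Sequencing substitution errors
are applied per base, *including inside the UMI*, so the Levenshtein merge
is genuinely exercised. Alignments are emitted directly as SAM (`NH:i:1`,
UMI in QNAME); an optional FASTQ path (UMI + GGGG motif + read, for the
inline layout) exists for end-to-end preprocessing tests.

Defaults — 50 genes × 20 molecules, 10 bp UMIs, 36 bp reads, 10 PCR
cycles, stutter probability 0.1, per-base error 0.001, half the genes
carrying a repeat of unit 1–3 bp — are desk-scale versions of a
tagmentation library: 36–50 bp reads and 10 bp UMIs are typical of the
protocols that exhibit the artefact, ~1 stutter event per lineage keeps
offsets in the 1–2 unit range that dominates real shift tables, and 0.1%
substitution error is routine Illumina quality. These sizes also keep the
whole test suite and acceptance analysis within a few minutes on one CPU;
they are stated here as the package's chosen study scale.

What the simulator does *not* emulate: transcriptome structure (splicing,
3' bias), cell barcodes, amplification-efficiency differences between
molecules, alignment ambiguity (every read is emitted as a unique,
correctly placed alignment), and any mechanistic sequence-level slippage —
stutter is offset bookkeeping, which is exactly the level the pipeline
consumes. Passing recovery tests on this generator therefore shows the
clustering/collapsing logic is correct under the stated error model, not
that real libraries contain no other failure modes.

### Ground-truth strata

`truth_compare()` contrasts pipeline gene counts with the simulated truth.
Exact recovery cannot be demanded of every gene, because the truth itself
sometimes makes it impossible; rather than average these cases away, each
gene is flagged:

* **UMI collision**: two molecules of one gene drew true UMIs within
  Levenshtein distance 2 of each other, so observed tags can merge at a
  coordinate or co-chain (the classic birthday-collision limit of UMI
  counting). Distance 2 is deliberately conservative: one sequencing error
  can bridge a distance-2 pair.
* **Risky UMI error**: a read's observed UMI differs from its molecule's
  true UMI in a way the per-coordinate merge cannot provably absorb —
  distance > 1 from the truth, or no strictly-more-abundant true-UMI reads
  of the same molecule at the same coordinate (so the erroneous tag can
  found or capture a representative). Per-coordinate merging can only
  correct errors that co-occur with the true tag at one position.
* **Stutter escape**: a molecule's realized coordinates contain an
  adjacent gap above `max_gap`, which gap-limited chaining cannot
  reunite — under-collapse inherent to any finite threshold, reported
  rather than hidden.

Genes with none of the flags form the *clean stratum*, in which collapsed
counts must equal the true molecule counts exactly — and do, across the
seeds and stutter grid the acceptance suite runs. The flags are
conservative (over-flagging shrinks the stratum but never excuses a real
defect in it).

## Numerical and design choices

* Phred encoding is fixed at offset 33; characters below `!` raise an
  error rather than silently re-interpreting the scale as offset 64.
* Reads with N inside the UMI pass if their quality passes; N is a literal
  fifth character in the edit distance, so it matches only itself.
* The motif bases after an inline UMI are removed by *count* (4 or 3 bp),
  not by motif matching; how often the expected GGG motif was present is
  reported so protocol mix-ups surface in logs.
* BED output uses standard 0-based half-open single-base intervals with
  the count in column 4. (A dialect writing start == stop also exists in
  the wild; the standard form is emitted because interval logic downstream
  is exact either way, and documented here once.)
* Observations overlapping several genes count for each by default
  (matching default intersect behaviour); `unique_only = TRUE` drops
  ambiguous sites. A cluster spanning a gene boundary is assigned by its
  modal coordinate in collapsed mode, while uncollapsed counting assigns
  each coordinate independently — the faithful reading of the two schemes
  being compared.
* Shift-density plots show sqrt(density) so the small flank proportions
  are visible; stored densities are untransformed and sum to 1.
* All outputs use stable sort orders, so re-running a configuration
  reproduces byte-identical tables.

## Limitations

* Cross-position UMI identity is exact; a fuzzy cross-position mode would
  merge slightly more but risks chaining unrelated molecules, and is
  deliberately not the default behaviour.
* The greedy merge is order-deterministic but, like all greedy policies on
  a non-transitive relation, not the unique fixed point; network-based UMI
  methods (directional adjacency graphs) are out of scope.
* Spliced alignments are keyed by POS only; reads whose 5' ends map across
  an intron boundary are not reconciled.
* The ANOVA is the classical equal-variance test; with strong
  heteroscedasticity across sizes its p-values are approximate (the
  direction of the trend, not the p-value, is the claim tested here).

## Problem sizes used by the test suite

Unit tests run on crafted instances of a handful of reads; property tests
use 1,000 random coordinate instances (≤ 200 positions) against a
brute-force connected-components oracle; recovery tests run the full
pipeline on 60 simulated libraries (50 genes × 20 molecules; stutter
probability 0, 0.1, 0.3 × seeds 1–20). These scales were chosen as the
package's desk-scale study conditions and complete in a few minutes.
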