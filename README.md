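# umishift

Detection and correction of the **read-mapping-shift artefact** in
UMI-tagged RNA-Seq (bulk and single-cell).

## The problem

A unique molecular identifier (UMI) gives every PCR copy of one input
molecule a shared random tag, so molecule counts can be recovered by
deduplicating on (UMI, mapping coordinate). That recovery silently assumes
reads at *different* coordinates come from *different* molecules. In
practice, reads sharing a UMI often map to a run of closely spaced
coordinates — most reads at a modal position, with diminishing numbers 1–3
bp up- and downstream, forming a bell-shaped **UMI-read cluster**. Uniform
spacings (strictly 1, 2 or 3 bp between adjacent positions) point at
repeat-stabilized PCR stutter on homopolymer/short-tandem-repeat
templates. Counting each (UMI, coordinate) pair as a molecule inflates
gene-level UMI counts; the correction is to **collapse** each cluster into
a single observation at its modal coordinate.

`umishift` is for anyone quantifying genes from UMI-tagged libraries who
wants counts robust to this artefact, or wants to measure how strongly
their own data exhibits it.

## The method

Given uniquely aligning reads (`NH:i:1`, UMI in the QNAME as
`_UMI:<seq>`):

1. at each (reference, strand, coordinate), merge UMIs within Levenshtein
   distance 1 (greedy, abundance-first — PCR/sequencing errors in the tag);
2. for each (reference, strand, UMI), chain sorted coordinates
   single-linkage wherever adjacent gaps ≤ `max_gap` (default 3 bp) —
   these chains are the UMI-read clusters;
3. collapse each cluster to one molecule observation at the modal
   coordinate (ties: leftmost);
4. quantify: pooled shift distributions (mode at offset 0, density sums
   to 1), strictly-*n* spacing classes, cluster-size summaries, gene count
   tables with and without collapsing (their ratio = apparent
   overexpression), and Shannon entropy
   *H* = −Σ *p(x)* log₂ *p(x)* / mutual information
   *I* = Σ *p(x,y)* log₂ *p(x,y)* / (*p(x) p(y)*) of modal reads by
   cluster size, with a one-way ANOVA across sizes.

A bundled simulator (`simulate_library()`) generates UMI-tagged libraries
with a parameterized per-cycle PCR-stutter random walk plus ground truth,
so the whole pipeline is testable without external data.

## Worked example

```r
library(umishift)

sim <- simulate_library(sim_config(seed = 42, stutter_prob = 0.2))
res <- run_umishift(sim$paths$sam, sim$paths$gff)

res$clusters
#> UMI-read clusters: 1145 clusters from 2900 unique alignments (max_gap = 3 bp)
#>   sizes: 1-5; total reads: 2900

shift_distribution(res$clusters)[6:8, ]
#>   offset reads    density
#> 6      0  2389 0.82379310
#> 7      1   100 0.03448276
#> 8      2   128 0.04413793

res$gene_table
#> Gene count table: 50 genes
#>   uncollapsed/collapsed ratio: median 1.091, max 2.550; 25 gene(s) > 1
#>  gene_id reads umis_uncollapsed umis_collapsed    ratio
#>  gene001    60               51             20 2.550000
#>  gene002    62               42             27 1.555556
#>  ...

truth_compare(res$gene_table, sim)$clean_exact_match_rate
#> [1] 1
```

Read it as: 2,900 reads deduplicate to 1,145 clusters; 82% of reads sit at
their cluster's modal coordinate and the rest within a few bp — the
artefact's bell shape. Without collapsing, gene001's apparent expression
would be inflated 2.55× (51 vs 20 molecules). In the ground-truth stratum
free of UMI collisions and uncorrectable tag errors, collapsed counts
recover the simulated molecule counts exactly.

Complexity of modal reads rises in stutter-prone templates:

```r
rec <- modal_read_complexity(res$clusters)
anova_by_cluster_size(rec, "H_bits")[c("F", "df")]
#> $F
#> [1] 134.0521
#> $df
#> [1]    4 1140
```

A thin CLI over the same functions is installed at
`system.file("scripts", "umishift", package = "umishift")`
(subcommands `run`, `simulate`, `preprocess`).

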