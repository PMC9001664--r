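# tcrclonics

Single-cell TCR repertoire analysis for clonal T cell disorders: clonotype
calling from paired-chain V(D)J contigs, clonality and diversity statistics,
cross-sample sharing, longitudinal clone dynamics, motif-based convergence
groups, and coupling of clonal structure to a transcriptome embedding — with
a fully ground-truthed synthetic cohort generator.

## Who this is for

Analysts of 10x Genomics single-cell V(D)J data (or AIRR rearrangement
tables) studying clonal expansions — for example in T-cell large granular
lymphocyte leukemia, where one or a few cytotoxic T cell clones dominate the
repertoire and their response to immunosuppression is read from paired
pre/post-treatment samples. The CDR3 region of the rearranged TCR serves as
a clone barcode; everything downstream is built on that identity.

## What it computes

* **Clonotypes** — per-cell representative chains (highest-UMI productive
  contig per locus), keyed by paired α+β nucleotide CDR3 by default
  (amino-acid, V/J-inclusive and β-only schemes available). *Expanded
  clones* are clonotypes with ≥ 10 cells.
* **Clonality / diversity** — Gini index
  G = Σᵢⱼ |xᵢ − xⱼ| / (2 n² x̄) of clone sizes; Shannon entropy
  H = −Σ pᵢ log₂ pᵢ; top-3 clone fraction; CDR3 length spectratype; and an
  OLS fit of the log-log complementary CDF P(X ≥ x), whose slope −γ
  summarizes the power-law structure of clone sizes.
* **Sharing** — pairwise counts of identical CDR3 clonotypes across
  samples, over all clones or each sample's top 200.
* **Dynamics** — outer join of a subject's two visits; clones classified
  increased / unchanged / decreased by a ±20% relative frequency change
  (closed band), with emergent and lost clones tallied separately.
* **Convergence groups (CRGs)** — GLIPH-style specificity groups on the
  pooled top-500 β CDR3s: flank-trimmed k-mers (k = 2–4) enriched ≥ 10-fold
  over a reference with resampling p ≤ 0.001, plus Hamming-distance-1
  near-identity; connected components with more than five distinct
  sequences, named after their dominant member. Includes the CMVpp65 motif
  panel (TGT, ATN, FQ, SSA, QTG) Fisher test.
* **Embedding coupling** — permutation test of within-group embedding
  coherence, Damerau-Levenshtein (OSA) CDR3 distance versus embedding
  distance correlation, and kNN batch-mixing entropy.
* **Synthetic cohorts** — power-law clone sizes (exact discrete CCDF
  x^−γ), chain dropout at the published detection medians (α 61%, β 95%),
  planted CDR3 motifs, clone-correlated embeddings, paired timepoints with
  per-clone fold changes, and the ground truth to verify all of the above.

## Worked example

```r
library(tcrclonics)

cfg <- sim_config(n_subjects = 4, clones_per_subject = 200, seed = 42)
sim <- generate_timepoints(generate_repertoire(cfg))   # pre + post visits
tabs <- clonotype_tables(sim)                          # per-sample clonotypes

diversity_metrics(tabs)
#>   sample_id  gini shannon n_clones n_cells top3_fraction powerlaw_slope
#> 1   S01_pre 0.679    4.93      138     501         0.455         -0.859
#> 2   S02_pre 0.513    5.77      130     334         0.332         -1.159
#> 3   S03_pre 0.376    6.33      125     222         0.203         -1.427
#> 4   S04_pre 0.336    6.77      143     241         0.112         -1.958
#> 5  S01_post 0.717    4.63      123     574         0.559         -0.821
#> 6  S02_post 0.466    6.39      140     336         0.199         -1.468
```

Each row is one sample: `gini` near 0 means an even repertoire and rises
with clonal dominance; `shannon` (bits) falls as diversity is lost;
`top3_fraction` is the share of keyed cells in the three largest clones;
`powerlaw_slope` is the fitted CCDF slope (−γ; shallower slopes mean
heavier clone-size tails). Here S01 — the most clonal subject — has the
highest Gini, lowest entropy, and shallowest slope.

```r
dynamics_summary(match_clones(tabs$S01_pre, tabs$S01_post))$counts
#> increased unchanged decreased
#>         2         2         2
```

Among S01's clones expanded at either visit, two grew by more than 20% of
their frequency, two stayed within ±20%, two shrank.

```r
sharing_matrix(tabs[1:4], "top_n", n = 200)
#>         S01_pre S02_pre S03_pre S04_pre
#> S01_pre     138       0       0       0
#> S02_pre       0     130       0       0
#> S03_pre       0       0     125       0
#> S04_pre       0       0       0     143
```

Off-diagonal zeros: clonotypes are subject-private at nucleotide identity
(the generator's default, matching the near-absence of public nucleotide
clonotypes between individuals); diagonals are each sample's clone count.

A thin command-line wrapper over the same functions is included at
`inst/scripts/tcrclonics.R` (subcommands `simulate`, `clonotype`,
`diversity`, `sharing`, `dynamics`, `crg`, `mixing`).

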