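---
title: "Clonality, convergence and dynamics of single-cell TCR repertoires"
author: "tcrclonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality, convergence and dynamics of single-cell TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrclonics)
```

## The problem

Clonal T cell disorders such as T-cell large granular lymphocyte leukemia
are driven by the expansion of one or a few cytotoxic T cell clones. Because
every T cell carries a practically unique T cell receptor (TCR), the
rearranged CDR3 region of the receptor works as a clone barcode: paired
single-cell V(D)J sequencing yields, per cell, the assembled alpha- and
beta-chain contigs from which clones, their sizes, and their dynamics under
treatment can be read off directly. `tcrclonics` implements that analysis
chain: contig QC and clonotype calling, clonality and diversity statistics,
cross-sample sharing, longitudinal clone dynamics, motif-based convergence
groups, and permutation tests linking clonal structure to a transcriptome
embedding. A synthetic cohort generator with full ground truth stands in for
patient data so that every stage is testable end to end.

## Clonotype model

A cell enters clonotyping when it has at least one productive TRA or TRB
contig with one or more UMIs (and, by default, the high-confidence flag set
when present; whether published repertoires excluded low-confidence contigs
is rarely stated, so this is exposed as a flag). Within a cell and locus the
*representative chain* is the contig with the most UMIs, ties broken by
contig id — the convention of the upstream assembler. Cells with extra
productive chains at a locus are counted and reported but never assigned
two clonotypes.

The default key scheme `nt_paired` joins the alpha and beta nucleotide CDR3
of the representative chains — the strictest reading of "identical TCR
alpha and beta chains". Schemes `aa_paired`, `nt_paired_vj` (adds V/J gene
names) and `beta_nt_only` are available; whether published expanded-clone
definitions include the gene segments is usually unstated, so the V/J
variant exists but is not the default. Under paired schemes, cells missing
either chain are unkeyed and excluded from the frequency denominator, so
clone frequencies always sum to one over keyed cells; raw cell counts are
reported alongside. An *expanded clone* is a clonotype with at least 10
member cells, the operational definition used across clonality studies of
T cell malignancies.

## Diversity statistics

For clone sizes $x_1,\dots,x_n$ the Gini index is

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed through the sorted $O(n \log n)$ identity and verified in the
tests against the $O(n^2)$ definition. $G$ is scale-invariant, 0 for a
perfectly even repertoire, and approaches 1 under extreme dominance. No
small-sample $n/(n-1)$ correction is applied by default (published
repertoire Gini values cite none); a flag enables it.

Shannon entropy $H = -\sum p_i \log_b p_i$ uses base 2 by default and is
configurable to natural log, because published entropy magnitudes often
leave the base unstated. Between-group *orderings* of $H$ are
base-invariant, which is why the package's checks compare orderings rather
than printed magnitudes.

The clone-size distribution is summarized by the log-log complementary CDF:
for each distinct size $x$ the point $(\log_{10} x, \log_{10} P(X \ge x))$
with $P$ over clones. The power-law slope is an ordinary least-squares line
through these points (optionally restricted to $x \ge$ `min_size`),
matching how such fits are drawn in repertoire figures; a maximum-likelihood
exponent estimator is deliberately out of scope. OLS on the CCDF carries a
small downward bias in the exponent from discreteness at small sizes; at
5000 clones the fitted exponent for a true $\gamma = 1.5$ law centers near
1.44, well inside the package's ±0.15 recovery band.

## Sharing and dynamics

Cross-sample sharing counts distinct clonotype keys present in two samples,
at nucleotide (default, strictest) or amino-acid identity, either over all
clones or each sample's top-$n$ by size (ties broken by key order so the
matrix is reproducible). The diagonal stores each sample's own clone count
under the mode.

Between a subject's paired visits, clones are matched by an outer join on
the key and classified by the relative change of their *frequency*:
increased if it grew by more than 20%, decreased if it shrank by more than
20%, unchanged inside the closed ±20% band. Frequencies rather than raw
sizes are compared so that different cell yields between visits do not
masquerade as expansion; absolute cell-count deltas are still reported
because published size-change ranges are cell counts. Clones absent at one
visit are *emergent* or *lost* and never enter the three proportional
classes — the published three-way counts are defined only by proportional
change, and inventing a rule for them would not be faithful. Summaries
default to clones expanded (≥ 10 cells) at either visit, mirroring the
usual focus on expanded clones; a flag lifts the restriction.

## Convergence groups

Distinct beta CDR3s that likely recognize the same antigen are grouped in
the GLIPH style. The top 500 beta CDR3s per sample are pooled; sequences
are trimmed of their first three and last two residues before k-mer work
(motifs in the conserved C…F framing are uninformative); and contiguous
k-mers (k = 2, 3, 4) are scored against a reference repertoire. A motif is
*enriched* when its per-sequence frequency is at least `fold_min` (10)
times the reference rate and its resampling tail probability — the add-one
fraction of 1000 size-matched reference draws containing at least as many
motif-bearing sequences — is at most 0.001. Motifs must occur in at least
two sample sequences: a singleton motif cannot link sequences into a group,
and novel singletons would otherwise flood the hit list with minimal
p-values.

The convergence graph has an edge between two pooled CDR3s when they share
an enriched motif or are equal-length at Hamming distance ≤ 1. Connected
components with **more than** five distinct sequences become groups (the
strict reading of "more than five"; a flag admits exactly-five components),
named `CRG_` plus their most abundant member. Per-edge evidence is retained
so groups are auditable, and per-sample cell counts give the top-5-sample
contribution.

The bundled reference is a synthetic naive repertoire drawn from the same
CDR3 model with no planted motifs — a stand-in, clearly labelled as such,
chosen so the package runs with no download; any user-supplied reference
file replaces it. The CMVpp65 motif panel (TGT, ATN, FQ, SSA, QTG) is
matched on the full, untrimmed CDR3 because the panel includes 2-mers that
trimming could remove; the over-representation test among expanded clones
of CMV-seropositive subjects is a two-sided Fisher exact test.

## Coupling to a transcriptome embedding

The embedding (typically 2-D t-SNE) is consumed, never computed. Coherence
of a cell group is tested by comparing its mean pairwise Euclidean distance
with the same statistic on random equal-sized cell subsets; the p-value
uses the add-one estimator $p = (1 + \#\{\text{null} \le \text{obs}\}) /
(n_{\text{perm}} + 1)$, one-sided for coherence by default since the claim
under test is that group cells sit *closer* (a two-sided option exists).
CDR3 dissimilarity uses the optimal-string-alignment variant of the
Damerau-Levenshtein distance (substitution, insertion, deletion, adjacent
transposition, each cost 1); the variant is stated because OSA can violate
the triangle inequality. Sequence-versus-embedding association is a
Spearman correlation over a seeded random sample of cell pairs. Batch
mixing is the mean per-cell Shannon entropy of batch labels among the 30
nearest neighbours, normalized by the log batch count so 1 means perfectly
mixed.

## The synthetic cohort generator

The generator produces what the analysis assumes and nothing more:

* **Clone sizes** are `floor` of a Pareto variate, giving the exact
  discrete law $P(X \ge x) = x^{-\gamma}$ truncated at `max_clone_size`;
  default $\gamma = 1.5$ with 300 clones per subject.
* **Chain dropout**: a cell retains an alpha chain with probability 0.61
  and a beta chain with probability 0.95 — the published detection medians
  for these libraries; 10% of alpha-bearing and 5% of beta-bearing cells
  carry a secondary chain with low UMI support, and 3% of cells emit a
  nonproductive contig, so the QC path is exercised.
* **CDR3s** are "C" + i.i.d. interior + "F" with Gaussian length
  (mean 14, sd 1.5, clipped to 8–22 residues). Nucleotide sequences are
  back-translated with the first codon per residue, deterministically, so
  nucleotide and amino-acid identity coincide in the generator while the
  key schemes still exercise both levels. There is no V(D)J recombination
  model: the analyses under test depend only on clone structure, motifs
  and lengths.
* **Planted motifs** are inserted at a random offset strictly inside the
  trimmed region of designated clones (by default the largest, so they
  reach the pooled top-500); planted clones draw lengths long enough to
  host the motif.
* **Timepoints**: each clone of a treated subject draws a class from a
  mixture (defaults: increased ×1.5–3, unchanged ×0.9–1.1, decreased
  ×0.2–0.7, lost, plus emergent clones at 5%). The recorded `class_true`
  is the ±20% classification of the *realized* frequency change — that is
  what a dropout-free pipeline run must reproduce exactly — while the
  drawn mixture component is kept separately.
* **Embedding**: clone centers $\mathcal N(0, \sigma_b^2 I)$, cells
  $\mathcal N(\text{center}, \sigma_w^2 I)$, batch = sample.
  $\sigma_b = 0$ is the null mode used to calibrate the permutation tests.
* **Sharing**: clones are subject-private by default
  (`cross_subject_overlap = 0`, matching the near-absence of public
  clonotypes at nucleotide identity); when overlap is enabled, copied
  clones take distinct donors so no subject carries two clones with the
  same receptor.

Everything is driven by a single mandatory seed; regeneration is
bit-identical, including written files.

What the generator does **not** emulate — sequencing error, allelic
inclusion beyond a fixed secondary-chain rate, realistic V/D/J gene usage,
thymic selection, batch structure in the embedding beyond labels —
delimits what passing tests show: they certify the statistical machinery
and its calibration, not robustness to artefacts absent from the model.
The published patient-cohort magnitudes (e.g. Gini near 0.34 in patients
versus 0.09 in controls) depend on the deposited data and unreported
parameters, so the package's checks reproduce *orderings* and *recovery
properties*, not printed values.

## Numerical choices

* Ties everywhere break lexicographically (clone keys, pooled sequences)
  so every output is order-invariant and reproducible.
* Frequency denominators are keyed cells; `sum(frequency) == 1` is tested
  to 1e-9.
* Permutation and resampling p-values use add-one estimators, never zero,
  valid under their nulls; all resampling is seeded and the seed is echoed
  in results.
* Verification problem sizes: 5000 clones × 10 seeds for exponent
  recovery; ~20,000 cells for dropout recovery (±0.02); 500 trials for
  permutation-test calibration; 20 seeds for planted-motif recovery and
  the patient/control orderings. These sizes make the Monte-Carlo bands in
  the tests comfortably tighter than the effects they check.
* Degenerate inputs error loudly and specifically: empty size vectors,
  zero denominators, single-batch mixing, all-identical CDR3s, Fisher
  tables with an empty margin, fewer than three distinct clone sizes for
  the power-law fit.

## A worked synthetic analysis

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 4, clones_per_subject = 200, seed = 42)
sim <- generate_timepoints(generate_repertoire(cfg))
tabs <- clonotype_tables(sim)

diversity_metrics(tabs)
sharing_matrix(tabs, "top_n", n = 200)
dynamics_summary(match_clones(tabs$S01_pre, tabs$S01_post))$counts

pooled <- pool_top_cdr3(tabs, 500)
hits <- enriched_kmers(pooled$cdr3_aa, make_reference_repertoire(10000),
                       seed = 1)
build_crgs(pooled, hits)

emb <- generate_embedding(sim)
mixing_entropy(emb, k_neighbors = 30)$mean_entropy
```

## Known limitations

* The OLS power-law fit is descriptive, as in repertoire figures; it is
  not a consistent estimator of the exponent and carries a small
  discreteness bias.
* OSA Damerau-Levenshtein can violate the triangle inequality; groups or
  correlations built on it inherit that property.
* The bundled enrichment reference is synthetic; conclusions about real
  repertoires require a real naive reference via the `reference` argument.
* kNN search in `mixing_entropy` is exact and chunked; it is quadratic in
  cell number and intended for embeddings up to a few tens of thousands of
  cells.
* Whether low-confidence contigs, V/J-inclusive keys, or pooled post
  visits best match any given published analysis is configurable but the
  defaults encode one defensible reading.
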