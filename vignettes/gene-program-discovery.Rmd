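---
title: "Robust gene-program discovery and organoid screen statistics with scprograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust gene-program discovery and organoid screen statistics with scprograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`scprograms` implements a complete desk-scale pipeline for discovering
*gene programs* — sets of coordinately expressed genes interpreted as cellular
states — from multi-sample single-cell UMI count data, and for the companion
statistics of organoid drug screens. The stages are:

1. cell/gene quality control and log2(TPM+1) normalization,
2. per-gene centering with negative clipping,
3. per-sample-line NMF across a range of ranks and extraction of top-50-gene
   programs,
4. a three-criteria robustness filter with greedy redundancy removal, UPGMA
   clustering on Jaccard similarity, and consensus signature genes,
5. per-cell program scoring against expression-matched background gene sets,
6. annotation against curated reference meta-programs (permutation
   confidence, hypergeometric overlap, BH FDR) and representative-gene
   selection against a SASP secretion table,
7. joint cross-dataset PCA with correlation-driven component-pair selection,
8. drug-screen statistics: viability normalization, z-scores, growth rates,
   median-effect fits and the Chou–Talalay combination index.

A synthetic-data generator with full ground truth stands in for real
droplet data so that every stage is testable end to end.

# The discovery model

## Normalization and the NMF substrate

Counts are scaled per cell to one million (UMI data carries no gene-length
term, so TPM here is counts-per-million) and transformed as
$E_{gc} = \log_2(\mathrm{CPM}_{gc} + 1)$. Each gene is then mean-centered
across cells and negative entries are set to zero. Clipping is what makes the
matrix a valid NMF input while preserving the information NMF needs: which
cells express a gene *above* its typical level. The per-gene means are stored
so centering is reversible.

QC applies five per-cell rules before normalization — total UMIs ≥ 500,
200 ≤ detected genes ≤ 8000, novelty score
$\log_{10}(\text{genes})/\log_{10}(\text{UMIs}) > 0.80$, mitochondrial count
fraction < 10% — then keeps genes detected in more than 1/1000 of the
retained cells. Two readings of "log10 genes per UMI" exist; the literal
$\log_{10}(\text{genes}/\text{UMIs})$ is negative for every UMI dataset and
would retain nothing at a 0.80 threshold, so the ratio-of-logs novelty score
is the default and the literal reading is available as
`qc_params(novelty_mode = "log_of_ratio")` for completeness. The UMI and
gene bounds are inclusive and the novelty and mitochondrial bounds strict,
exactly as stated; the mitochondrial rule uses the fraction of *counts*,
the standard convention. Gene filtering runs on the post-cell-filter matrix.

Note that the novelty threshold implicitly assumes a genome-scale gene
universe: with $G$ genes total, no cell can exceed a novelty of
$\log_{10} G / \log_{10}(\text{UMIs})$. On compact simulated universes
(hundreds of genes) the full-scale thresholds are unsatisfiable, so
pipeline-level tests on synthetic data use thresholds scaled to the universe
(minimum 50 detected genes, novelty 0.5, mitochondrial rule disabled). The
printed defaults remain the package defaults and their boundary behavior is
tested on hand-built fixtures.

## NMF and program extraction

Each sample line is factorized separately: $A \approx WH$ with
$A \in \mathbb{R}_{\ge0}^{G \times C}$, rank $K$ running over 6–9 by default,
giving $6+7+8+9 = 30$ programs per line. The solver is Frobenius
multiplicative updates from an NNDSVD start whose zero entries are filled
with small seeded random values (zeros are absorbing under multiplicative
updates, so they must be broken; the seeded fill makes every run
reproducible). Convergence stops at a relative error decrease below
$10^{-4}$ or 500 iterations. No established NMF implementation is a package
dependency here because the factorization, and the consensus machinery on
top of it, are the core method of the package.

A program is a component's top 50 genes by basis coefficient, ordered by
non-increasing coefficient with ties broken by gene id (determinism).
Matrices with fewer than 50 genes yield short programs flagged as such, and
all overlap thresholds stated "out of 50" rescale proportionally
(`ceiling(threshold/50 * shorter list)`) for short lists.

## The robustness criteria

A program is *robust* when it satisfies both:

1. it shares ≥ 35 of its top 50 genes with a program of a **different rank**
   in the **same line** (stability across $K$), and
2. it shares ≥ 10 of its top 50 genes with a program in **any other line**
   (recurrence across samples).

Both bounds are inclusive ("at least"). Robust programs are then ranked by
their similarity to other lines' programs and scanned in decreasing order;
a program is kept unless an already selected program *from the same line*
shares **strictly more than** 10 genes with it. The deliberate contrast
between the inclusive "at least 20%" of criterion 2 and the strict ">20%"
of the redundancy rule is preserved. The ranking statistic is the maximum
Jaccard index to any other-line program (the simplest faithful reading;
the mean of per-line maxima is available via
`consensus_params(rank_statistic = "mean_of_maxima")`). Rank ties break by
(line, rank, component) so selection is deterministic.

Selected programs are clustered by average-linkage (UPGMA) agglomeration on
distance $1 - J$ (Jaccard), and the tree is cut to a requested number of
clusters — the reference analysis defined 7 manually; a count-based cut is
the closest deterministic analogue, and the `hclust` tree is returned so any
other cut can be taken. A cluster's *signature genes* are those present in
at least 40% of its member programs (count threshold
$\lceil 0.4\,n \rceil$), ordered by occurrence then id.

Two scale caveats discovered during validation are worth knowing. First,
NNDSVD initialization makes components at neighboring ranks highly similar,
so criterion 1 rejects little; discrimination comes mostly from criterion 2.
Second, criterion 2's 10-gene bound assumes a genome-scale universe: with
only $G$ genes, two random top-50 lists already share $2500/G$ genes in
expectation, and the shared abundance hierarchy between lines pushes the
observed overlap higher. On a 200-gene universe nearly everything passes
criteria 1–2 and the greedy redundancy stage does the filtering; at 2000+
genes criterion 2 alone empties an unstructured collection. Tests place each
claim at a scale where it is actually informative.

## Per-cell program scoring

For a query set $Q$, all genes are ranked by mean expression and divided
into 30 equal-frequency bins; each of 1,000 background sets replaces every
query gene with a random gene from the same bin (without replacement within
a set when the bin allows). This is the standard expression-matched
control-gene scheme; it guarantees every background set reproduces the
query's per-bin histogram. For each cell the mean per-gene-centered
expression of $Q$ is compared with each background set's, and

$$p = \frac{1 + \#\{\text{backgrounds strictly above } Q\}}{1 + N},\qquad
  \text{score} = -\log_{10} p$$

with ties counting as not exceeding. The pseudocount makes $p = 0$
impossible, so the score is always finite. Raw scores are rescaled linearly
to $[0,1]$ per program across all scored cells — scores are compared across
lines downstream, which implies a shared scale; per-line rescaling is
available (`rescale = "per_line"`). Under an exchangeable null the p-values
are approximately uniform; the test suite verifies this with a
Kolmogorov–Smirnov check at 500 cells and 1,000 backgrounds.

## Annotation against reference meta-programs

Each discovered cluster is compared with every reference set by (i) the mean
Jaccard index between its member programs' top-50 lists and the reference
and (ii) the Pearson correlation of per-cell scores. Significance uses a
pooled permutation null: each permutation redraws every member program's
gene list uniformly from the universe, and statistics are pooled across all
(cluster, reference, permutation) triples before taking the 99.9% quantile.
Pooling is the only way 100 permutations can support a 99.9% threshold —
a per-pair quantile would need 1,000+ draws. For the correlation null,
re-deriving a 40% consensus signature from independent random lists is
almost always empty, so the null scores one random signature-sized gene set
per cluster and permutation instead; the Jaccard null follows the
member-list permutation exactly. Hypergeometric overlap tests (upper tail)
with Benjamini–Hochberg adjustment run alongside; the universe defaults to
the genes of the scored matrix and is overridable, since overlap p-values
are only interpretable relative to a stated universe.

Representative-gene selection for a secretory program takes the union of
two routes: genes exceeding a log2 fold-change of 2 (strict) in at least one
senescence condition of a SASP secretion table *and* detected in every
sample line (detection frequency 1; a per-cell-fraction reading is available
via `detection_frequency(mode = "per_cell")`), plus genes shared with any
companion program. Each output gene is tagged with its route.

## Joint PCA across datasets

Datasets are restricted to shared genes and centered per gene *within each
dataset*, which cancels dataset-specific baseline offsets without any
model-based batch correction (deliberately out of scope). PCA runs on the
top 4,500 genes by pre-centering mean expression (centered means are zero by
construction, so the ranking must use the stored means; mean rather than
total expression is used, which is equivalent for equal-size datasets). The
visualization pair is chosen deterministically: among the first 10
components, the pair maximizing the minimum |r| against the two programs of
interest, requiring |r| > 0.35 for both — a two-sided rule, so strong
anti-correlation qualifies. When nothing qualifies the full correlation
table is returned with an explicit "none" status rather than a forced pick.

# Drug-screen statistics

Viability is each well's ATP signal over the mean control (DMSO) signal.
The z-score is (mean drug ATP − mean control ATP)/SD(control ATP) with the
sample (n−1) estimator — the convention when only a handful of control wells
exists. Growth rate is the day-6/day-4 mean-size ratio of the drug wells
over that of the control wells; evaluating the controls against themselves
gives exactly 1.

Dose response uses the median-effect model $f_a/f_u = (D/D_m)^m$, fitted as
a linear regression of $\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$, so
$m$ is the slope and $D_m = 10^{-\beta_0/m}$. Measured affected fractions
are clipped to [0.005, 0.995] before the log-odds transform (the transform
is undefined at 0/1) and clipped points are flagged. The combination index
at an observed combination effect $f_a$ is
$\mathrm{CI} = d_1/D_{x,1} + d_2/D_{x,2}$ with
$D_{x,i} = D_{m,i}(f_a/(1-f_a))^{1/m_i}$ — the mutually exclusive form; the
nonexclusive variant adds $d_1 d_2/(D_{x,1} D_{x,2})$ and is a switch.
Log CI below 0 is synergy, above 0 antagonism; because an exact zero is
meaningless under measurement noise, |log10 CI| ≤ 0.1 is *called* additive
while the raw value is always reported. Allograft volumes use the modified
ellipsoid formula $V = 0.5236\,L W^2$.

# The synthetic-data generator

`generate_counts()` draws lognormal relative gene abundances (one vector
shared by all lines, as lines share a genome), uniform per-cell expected
library sizes, and negative-binomial counts with mean–dispersion
parameterization (dispersion → 0 recovers Poisson). A configurable fraction
of genes is flagged mitochondrial and named with the conventional `mt-`
prefix so QC can filter by mask or by name. Planted programs multiply the
expected counts of a disjoint gene set by the effect size in a fixed-size
random cell subset of each carrying line; the generator does **not**
renormalize library sizes afterwards, so the active/inactive expected-count
ratio equals the configured multiplier exactly — the property program
recovery depends on — at the cost of active cells having larger totals (the
library-size range is therefore only guaranteed for unstructured
configurations, and is tested there). Rank-unstable programs split their
effect across two half-strength gene subsets active in two partially
overlapping cell subsets, providing a true negative for cross-rank
filtering. Ground truth (gene lists, active cells) is returned and written
as GMT plus a cell-label table.

What the generator does *not* emulate: doublets, ambient RNA, batch effects,
cell-cycle structure, or realistic gene–gene correlation beyond the planted
programs. Passing recovery tests therefore demonstrates the pipeline's
machinery — not that real tissue programs are identifiable at these sample
sizes.

`generate_plate()` simulates screen plates: control wells at a configured
ATP baseline, drug wells following the median-effect curve scaled by a
maximum effect, organoid growth suppressed by the same viability factor
(which makes the growth-rate statistic round-trippable), and optional
relative Gaussian noise. At least three control wells are required, matching
the z-score's need for a control SD.

# Problem sizes, determinism and numerical choices

- Test and example runs use compact sizes chosen to exercise every code
  path: 3 lines × 300 cells × 200 genes for recovery runs, 2,000 genes where
  cross-line chance overlap must stay below criterion 2, 500 cells × 1,000
  backgrounds for calibration, 30-program collections for consensus.
- Every stochastic operation takes an explicit seed; `run_pipeline()` derives
  per-stage seeds deterministically from the global seed and stage name, and
  reruns are byte-identical (hash-verified in the tests).
- NMF: NNDSVD + multiplicative updates, `tol = 1e-4`, `max_iter = 500`,
  denominators guarded by machine epsilon; the error trace is returned and
  is non-increasing.
- Ties: gene-coefficient ties break by gene id; greedy-selection rank ties
  by (line, rank, component); score ties in the background comparison count
  as not exceeding.
- Degenerate inputs: empty QC results return an explicit empty status; a
  constant gene centers to zeros; constant score vectors rescale to zero and
  produce NA correlations, which the permutation null drops.

# Known limitations

- The tree cut is by cluster count; the reference analysis' manual cluster
  definition cannot be automated and different counts can change signatures.
- The pooled permutation null assumes exchangeability of (cluster,
  reference) pairs under permutation; heterogeneous set sizes make the null
  conservative for small sets.
- Criterion 1 has little discriminative power under NNDSVD initialization
  (see above); on real genome-scale data criterion 2 and the redundancy
  scan carry the selection, which matches how the filter behaves here.
- The growth-rate coupling in the plate simulator is a modeling convenience;
  real organoid growth is not proportional to end-point viability.
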