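---
title: "Identifying driver patterns from integrated expression, copy-number and mutation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying driver patterns from integrated expression, copy-number and mutation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermod)
```

# The problem

Tumors that resist or respond to a drug differ in expression programs that
are themselves driven by genomic lesions — copy-number changes and somatic
mutations — in a comparatively small set of driver genes. Given matched
expression, CNV and mutation profiles for a resistant and a sensitive
sample group, `drivermod` identifies *driver patterns*: candidate driver
genes ("modulators"), the co-expression modules whose expression they
predict, and whether each modulator's own expression tracks its genomic
dosage (dosage-sensitive, DSG) or not (dosage-resistant, DRG).

This vignette explains the model behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic generator does
and does not emulate, and the numerical and design choices that were open.

# Stage models and assumptions

## Differential screening

Expression differences between groups are scored per gene with the
one-dimensional Earth Mover's Distance between the two groups' normalized
histograms, which is sensitive to distributional differences beyond a mean
shift — appropriate for heterogeneous tumor cohorts. On a shared binning,
the minimum-cost transport reduces to the summed absolute difference of
cumulative histograms times the bin width, which is how `emd_statistic()`
computes it (and how the test-suite oracle independently recomputes it).

Significance comes from label permutations. The same shuffles are applied
to every gene within a permutation, preserving inter-gene correlation, and
p-values use the add-one estimator (b+1)/(B+1), so a constant gene gets
p = 1 rather than 0/B. Benjamini–Hochberg converts these to q-values; the
screen keeps genes at q < 0.1. Binning is Freedman–Diaconis on the pooled
values with a floor of 10 bins: scale-adaptive, and fixed per gene across
permutations so observed and null statistics share a support.

CNV states are called from gene-level log2 ratios at a threshold of 0.3
(amplified above +0.3, deleted below −0.3, strict inequalities; values at
the boundary are normal). Genes enter the mutation analysis when their
within-group amplification or deletion frequencies differ by strictly more
than 0.20, or (for somatic calls) when mutated in strictly more than 2% of
either group's samples. "Strictly more than" follows the thresholds'
definitions; boundary cases are excluded. Segment-level input is mapped to
genes by maximal base-pair overlap (ties to the first segment in file
order), genes covered by no segment being treated as copy-normal.

## The gene-length bias filter

A gene's chance of carrying a passenger mutation grows with its cDNA
length, so recurrently mutated long genes are suspect. The filter
estimates the length-expected mutation probability with a *probability
weight vector* (PWV): logistic regression of per-sample mutation status on
a cubic spline of log cDNA length with six interior knots at log-length
quantiles, projected onto monotone non-decreasing values by isotonic
regression over the length order. The log scale is used because cDNA
lengths are heavily right-skewed (roughly log-normal); knots at quantiles
of a raw-scale covariate would crowd into the short-length mass.
Canonical-link logistic regression makes the mean fitted probability equal
the observed mutation proportion, and the isotonic projection (an equal
weight least-squares projection that contains the constants) preserves
that calibration exactly.

Each sample's observed mutation set is then re-drawn `reps = 1000` times
without replacement from the gene universe with selection probability
proportional to the PWV, and `fre` is the fraction of replicates in which
a gene is drawn. Genes with `fre` strictly above 0.05 are removable as
length-explainable; genes at or below are retained.

Two readings of `fre` aggregation are possible, and the package makes the
choice explicit. Counting a gene once per replicate if it appears in *any*
sample's re-drawn set ("union") saturates when the cohort is large: with
hundreds of samples the union of weighted draws covers nearly the whole
universe every replicate, every gene's `fre` approaches 1, and the filter
removes everything — including short, recurrent drivers. The default is
therefore the per-sample mean: `fre` then estimates the length-predicted
per-sample mutation probability, directly comparable to the 5% threshold,
and matches the per-sample design of resampling-based length filters. The
union reading remains available via `aggregate = "union"`.

Within the pipeline the PWV is fitted on, and the resampling applied to,
*somatic* calls only: cDNA length is a model of point-mutation target
size, not of segmental copy-number involvement. The removal rule is then
applied to the whole CNV + somatic mutation gene pool.

## Co-expression modules

The expression network is unsigned: similarity is the absolute Pearson
correlation, raised to a soft-threshold power β ≥ 1 so that weak
correlations are suppressed smoothly. β is chosen as the smallest
candidate in 1..20 whose connectivity distribution fits a decreasing
power law with R² ≥ 0.8 (slope-signed), falling back to 6 — a
conventional default for unsigned networks — with a warning when no
candidate qualifies.

The topological overlap matrix combines direct adjacency with shared
neighbors,

$$\omega_{ij} = \frac{\alpha_{ij} + u_{ij}}{\min(m_i, m_j) + 1 - \alpha_{ij}},
\qquad m_i = \sum_{k \ne i} \alpha_{ik},
\qquad u_{ij} = \sum_{k \ne i,j} \alpha_{ik}\alpha_{kj},$$

with the diagonal fixed at 1 by convention and the shared-neighbor sum
excluding both endpoints. Modules come from average-linkage hierarchical
clustering on 1 − ω with a *static* cut at a fixed fraction (default 0.99)
of the maximum merge height; clusters below `min_module_size` (default 20)
are merged into the unassigned "grey" class. A static cut was chosen over
a dynamic branch-cutting heuristic because it is fully deterministic,
easily stated, and adequate for the block-structured correlation this
analysis targets; both the height fraction and the minimum size are
configuration keys. Surviving modules are labeled in decreasing size with
the conventional color order (turquoise, blue, brown, yellow, green, ...).

Each module is summarized by its eigengene — the first principal component
across samples of the per-gene z-scored module submatrix, unit norm, sign
oriented so its mean correlation with members is non-negative. Module
membership of a gene is its correlation with the eigengene, and gene
significance GS is the absolute point-biserial correlation with the binary
response (resistant = 1), so GS = 0 means no linear association with drug
response.

## Mutation network and candidate modulators

The binary mutation matrix **A** (samples × genes) marks a called CNV
(state ±1) *or* a somatic mutation. Vertices of the mutation network are
genes with mutation frequency h = m_i/m at or above `min_vertex_weight`
(default 0.02, mirroring the 2% screen); the edge weight between two genes
is

$$V_{ij} = \frac{\#\{s: \text{exactly one of } i,j \text{ mutated}\}}
               {\#\{s: \text{at least one mutated}\}},$$

which is 0 for perfectly co-occurring genes, 1 for mutually exclusive
ones, and algebraically equals 1 − Jaccard(support_i, support_j). Pairs
with no mutated sample have no edge rather than a zero weight.

Candidate modulators are selected by clustering vertices with V as the
pairwise distance (average linkage), so co-mutated genes — which tend to
act in one lesion context — fall into the same cluster, then taking the
`top_per_cluster` genes by h (gene id as tie-break) from each of
`n_clusters` clusters. The clustering method, cluster count (default 20)
and per-cluster depth (default 40) are deliberate, documented choices: the
analysis they implement ("cluster the mutation network, take recurrent
representatives") admits many concrete realizations, and these defaults
produce pools of a few hundred genes on cohort-scale data. The pipeline
clamps `n_clusters` to the vertex count.

## Module-network learning

Each module's *regulatory program* is a binary regression tree whose
decision nodes test one candidate modulator's mutation status and whose
leaves model the member genes' expression in the routed samples. The model
score is

$$\log P(C, N) = \sum_{\text{modules}} \sum_{\text{member genes}}
  \sum_{\text{leaves}} \operatorname{lml}(\text{gene's values in leaf})
  \;-\; \lambda \cdot \#\text{decision nodes},$$

where lml is the closed-form marginal likelihood under a conjugate
normal-gamma prior (defaults μ₀ = 0, κ₀ = 1, α₀ = 1, β₀ = 1 on per-gene
z-scored expression) and λ is the structure penalty, default
½·log(total observations) in the spirit of BIC. Scoring each member
gene's leaf block as its own normal-gamma unit makes the objective
*additive over genes*. That additivity is what guarantees the EM is
well-behaved: reassigning every gene to its argmax module cannot decrease
the total, and the M-step keeps the previous tree whenever the freshly
learned greedy tree does not improve the penalized score on the new
membership, so the score trace is provably non-decreasing. (Pooling all
member genes' values into a single leaf likelihood — the main alternative
reading — breaks exactly this guarantee under parallel reassignment, which
is why the factorized form is the package's model.)

Trees are learned greedily root-to-leaf: every unused modulator's binary
split is scored, the best accepted only if its gain exceeds the penalty,
ties broken by modulator id; depth is capped (default 3) and leaves must
route at least `min_leaf = 5` samples. Hard (classification) EM matches
the discrete "each gene reassigned" semantics; a gene whose best program
scores below the single-leaf background model stays where it is,
preventing collapse of sparsely supported modules. Splits test mutation
status only — the modulators are mutation-derived by construction;
expression-threshold splits are out of scope. Genes appearing in any
decision node are the identified modulators; one modulator may regulate
several modules, which is how shared-modulator driver patterns arise.

## Dosage sensitivity

For each modulator, expression is related to its genomic dosage: the CNV
log2 ratio for CNV-derived genes, the 0/1 mutation status for
somatic-derived genes. A LOESS fit (span 0.75, degree 2 — the
conventional defaults of local polynomial regression; evaluated exactly
with the direct surface rather than an interpolation grid) is read off at
n isometric points spanning the dosage range, and the monotonicity of
those fitted values is

$$M = \frac{2}{n(n-1)} \sum_{i<j} S_{ij}, \qquad
S_{ij} = \operatorname{sign}(s_j - s_i),$$

with differences within `tie_eps = 1e-9` treated as ties — without a tie
tolerance the "equal" branch of the sign function has measure zero in
floating point. The normalization 2/(n(n−1)) counts strict pairs i < j.
The number of evaluation points defaults to min(50, sample count): n here
is the resolution at which the curve's shape is summarized, and 50 points
resolve any shape a span-0.75 local fit can produce. The OLS slope K
quantifies the linear relationship, and

$$DS = M \times |K|$$

combines direction-consistency with effect size; note |DS| ≤ |K| always,
and for noiseless y = ax + b, DS = a exactly. Scores at or outside
(−0.25, 0.25) are classified DSG, scores strictly inside DRG. The
direction follows the method's semantics — near-zero slopes mean
dosage-*resistant*, slopes above 1 dosage-*sensitive*, and "a larger DS
indicates stronger dosage sensitivity" — the boundary case |DS| = 0.25
counting as DSG; the literal inverse reading is available as
`direction = "inside_dsg"`. Binary-dosage genes fall back to the
least-squares line for the curve (a two-level covariate cannot support a
local quadratic), making M = sign(K) there.

# The synthetic generator

`synth_config()` / `generate_bundle()` emulate the study design this
analysis expects, with planted ground truth for every stage:

* **Two labeled groups** — defaults 60 resistant + 60 sensitive samples.
* **Modulators** (default 10, cDNA 1–3 kb): mutated per sample with
  group-dependent rates (0.5 resistant / 0.2 sensitive), so differential
  screens have signal; ~70% carry the lesion as CNV (amplification or
  deletion, |log2| in 0.4–0.8), the rest as somatic mutations.
* **Modules** (default 5, of 20–30 genes): member expression equals the
  leaf mean of the module's planted tree over its modulators' statuses
  (for modulators m₁..m_k the mean is e·Σⱼ 2^(k−j) s_j, effect size e = 2
  log2 units) plus N(0, 0.5²) noise. Optionally the first modulator also
  drives the second module, planting a shared-modulator pattern.
* **Length-biased passengers** (default 20): cDNA lengths are log-normal
  with median 2 kb (σ_log = 1); passengers are drawn from the top length
  decile, and every non-modulator gene mutates per sample with probability
  length × 0.01/kb — the artifact the length filter exists to remove.
* **Dosage coupling**: half the modulators have expression
  slope × dosage + noise with slopes in [1, 2] (DSG by construction); the
  rest are expressed independently of their lesion (DRG).

Identical seeds give bit-identical bundles, and `write_bundle()` emits
every on-disk format the pipeline reads (expression TSV, SEG with segments
extended 250 bp into the intergenic gaps so that segment–gene mapping is
exercised nontrivially, BED, MAF, labels, lengths, ground-truth JSON).

The generator deliberately does **not** emulate: realistic genomic
coordinates or linkage, platform-specific noise (probe effects, GC bias,
batch structure), subclonal or allele-specific copy number,
mutation-type-specific rates, or correlated co-mutation beyond what the
group labels induce. Passing tests on this generator therefore show that
each stage recovers the structure it is designed for under calibrated
noise — not that the pipeline is robust to every artifact of real tumor
cohorts.

# Numerical choices and degenerate inputs

* Threshold comparisons tied to "more than" phrasings are strict; the
  resampling filter retains `fre` exactly 0.05, the DS classifier counts
  |DS| exactly 0.25 as DSG (documented boundary conventions).
* EMD bins: Freedman–Diaconis with a 10-bin floor; constant genes score 0
  with q = 1 rather than erroring.
* The TOM computation zeroes the adjacency diagonal before forming
  connectivities and shared-neighbor sums, which implements the
  k ∉ {i, j} index convention via plain matrix multiplication.
* Eigengenes error on zero-variance members (they cannot be z-scored);
  the pipeline drops zero-variance genes before the co-expression stage.
* Tree learning breaks score ties deterministically by modulator id;
  reassignment ties stay with the current module. A split must improve the
  penalized score by more than 1e-12 to be accepted, avoiding
  floating-point churn.
* Isotonic projection of the PWV uses `stats::isoreg` on the
  length-ordered fitted probabilities; weights are clamped to
  (1e-12, 1 − 1e-12) to keep them strictly inside (0, 1).
* Per-stage seeds are derived deterministically from the single global
  seed, so a stage rerun in isolation reproduces its in-pipeline stream;
  derived seeds stay below 2³¹ − 1.
* The per-sample resampling exploits that a sample's draw distribution
  depends only on its mutation count: draws are shared across samples with
  equal counts, which changes nothing statistically (the mean-aggregate
  `fre` is an average of per-count inclusion frequencies) and makes 1000
  replicates fast.

# Problem sizes in the test suite

The suite validates the implementation oracles exactly (brute-force TOM on
10-gene matrices, pairwise monotonicity loops, CDF-based EMD,
Student-t prior predictive for the normal-gamma marginal) and the
scientific behavior on generator scales chosen to keep the full suite
within a few minutes: default 200-gene/120-sample bundles for pipeline,
EM-monotonicity, module-recovery, length-filter and dosage checks (20
seeds each), and 60-gene null bundles (50 seeds) for false-selection-rate
control of the EMD screen. These sizes are the package's validation
conditions, not limits of the implementation; the stages are matrix- and
tree-based and scale to cohort-sized inputs.

# Known limitations

* The co-expression stage materializes dense gene × gene matrices;
  beyond ~20k genes a block-wise TOM would be needed and is not provided.
* The mutual-exclusivity edge weight is descriptive; no per-pair
  permutation test of exclusivity significance is performed.
* The candidate-modulator clustering is one documented realization of
  "cluster the mutation network"; different cluster counts change the pool
  and are exposed as configuration, not auto-tuned.
* Hard EM finds a local score optimum dependent on the co-expression
  initialization; no restarts or structure averaging are attempted.
* GO/KEGG enrichment of the DSG/DRG lists is out of scope;
  `export_enrichment_input()` writes plain gene lists for external tools.
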