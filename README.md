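# drivermod

Identification of candidate **driver genes (modulators)** and the gene
modules they regulate in drug-resistant versus drug-sensitive tumors, by
integrating gene expression, copy-number variation (CNV) and somatic
mutation profiles. The motivating setting is platinum response in ovarian
cancer, where resistant and sensitive tumor groups are compared across all
three data types; the package works on any two-group multi-omics design
with the same shape.

## Who this is for

Computational biologists who have matched tumor profiles — an expression
matrix (genes × samples, log scale), gene- or segment-level copy number
(SEG + BED, or a gene × sample log2-ratio matrix), somatic calls (MAF or a
binary matrix), a resistant/sensitive label per sample and cDNA gene
lengths — and want a reproducible, testable implementation of the
module-network driver analysis rather than a one-off script stack.

## The method

1. **Differential screening.** Per-gene Earth Mover's Distance (EMD)
   between the two groups' expression distributions, with permutation
   p-values (shared label shuffles across genes) and Benjamini–Hochberg
   q-values; genes with *q* < 0.1 enter the co-expression analysis. CNV
   genes are called amplified/deleted at |log2 ratio| > 0.3 and kept when
   the within-group amplification or deletion frequencies differ by more
   than 20%; somatic genes are kept when mutated in more than 2% of either
   group.
2. **Gene-length bias filter.** Long genes accumulate passenger mutations
   in proportion to their cDNA length. A probability weight vector (PWV) is
   fitted by logistic regression of per-sample mutation status on a
   monotone cubic spline of log cDNA length (six knots), and each sample's
   mutation set is re-drawn 1000 times with selection probability
   proportional to the PWV. Genes selected in more than 5% of replicates
   (`fre` > 0.05) are explainable by length alone and removed.
3. **Co-expression modules.** Unsigned weighted network from
   s<sub>ij</sub> = |cor(x<sub>i</sub>, x<sub>j</sub>)|, soft-thresholded
   as α<sub>ij</sub> = s<sub>ij</sub><sup>β</sup> (β picked by scale-free
   fit), combined into the topological overlap matrix
   ω<sub>ij</sub> = (α<sub>ij</sub> + u<sub>ij</sub>) / (min(m<sub>i</sub>, m<sub>j</sub>) + 1 − α<sub>ij</sub>),
   then average-linkage clustering on 1 − ω with a static cut; modules get
   the conventional colors (turquoise, blue, brown, ...), eigengenes and
   per-gene trait significance GS<sub>i</sub>.
4. **Mutation network.** A binary matrix **A** (samples × genes) marks a
   called CNV or somatic mutation. Vertices carry h<sub>i</sub> =
   m<sub>i</sub>/m (mutation frequency); edges carry the mutual-exclusivity
   weight V<sub>ij</sub> = #(exactly one mutated) / #(at least one
   mutated). Clustering the vertices on V groups co-mutated genes; the
   top-recurrence genes per cluster form the candidate modulator pool.
5. **Module networks.** For each module a regulatory program — a binary
   regression tree whose decision nodes test one modulator's mutation
   status — is learned greedily under the normal-gamma marginal likelihood
   with a per-node complexity penalty, and genes are reassigned to their
   best-predicting program (classification EM on
   log P(C, N) = log P(C|N) + log P(N)); the score trace is
   non-decreasing by construction. Decision-node genes are the identified
   modulators.
6. **Dosage sensitivity.** For each modulator, expression is regressed on
   its dosage (CNV log2 ratio, or mutation status for somatic-derived
   genes): a LOESS curve evaluated at n isometric points gives the
   monotonicity M ∈ [−1, 1]; the OLS slope gives K; DS = M × |K|.
   |DS| ≥ 0.25 ⇒ dosage-sensitive gene (DSG), otherwise dosage-resistant
   (DRG). Driver patterns combine each module's members with its
   modulators and their dosage class.

A synthetic multi-omics generator (`generate_bundle()`) plants all of this
structure — tree-regulated modules, group-dependent modulator lesions,
length-biased passengers, dosage-coupled and decoupled modulators — so
every stage is validated against known ground truth.

## Worked example

```r
library(drivermod)

bundle <- generate_bundle(synth_config(seed = 7))   # 200 genes, 60+60 samples
report <- run_pipeline(bundle, pipeline_config(seed = 7))
print(report)
```

```
Driver-pattern report
  gene counts by stage:
    universe                200
    expression_selected     136
    cnv_selected              6
    somatic_selected        133
    length_filtered          86
    modulator_pool           73
    module_genes            130
    learned_modules           5
    modulators               10
    dsg                       4
    drg                       6
```

The counts trace each screen: 136 of 200 genes differ in expression
between the groups (EMD q < 0.1); the combined CNV + somatic mutation pool
shrinks to 86 genes after the length filter; the mutual-exclusivity
network yields a 73-gene candidate pool; EM learning over the 5 detected
co-expression modules places 10 modulators in decision nodes; dosage
analysis classifies 4 as DSG and 6 as DRG. The per-modulator table shows
why:

```r
print(report$dosage)
```

```
    gene          M           K          DS class
1  G0001  0.9591837  1.45330379  1.39398527   DSG
2  G0002  0.8024490  1.05693857  0.84813927   DSG
3  G0003  1.0000000  1.85284664  1.85284664   DSG
5  G0006  0.3093878  0.04263905  0.01319200   DRG
8  G0009  1.0000000  0.04594893  0.04594893   DRG
...
```

G0001–G0003 track their copy number (slope |K| > 1, monotone LOESS, DS
well outside ±0.25); G0006/G0009 are expressed independently of their
lesions (K ≈ 0 ⇒ DS ≈ 0). In this bundle the planted truth
(`bundle$truth`) confirms 9 of the 10 extracted modulators and all DSG
calls. On-disk inputs are supported through `write_bundle()` /
`read_bundle()` (TSV/SEG/BED/MAF), and
`inst/scripts/drivermod.R` wraps `simulate` and `run-all` for shell use.

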