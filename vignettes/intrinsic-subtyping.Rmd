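---
title: "Methods: discovery and single-sample classification of intrinsic subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery and single-sample classification of intrinsic subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(criskit)
```

# The problem and the model

Bulk tumour expression is a mixture: cancer-cell transcripts plus
transcripts from fibroblasts, endothelium and immune infiltrate, in
proportions that vary from sample to sample. Unsupervised subtyping of
bulk profiles therefore tends to rediscover stromal content rather than
cancer-cell biology. This package implements a pipeline designed for the
opposite regime: expression data in which the stromal component is absent
or quantifiable (the canonical case is patient-derived xenografts, where
the stroma is murine and invisible to human-specific probes), from which
**cancer-cell intrinsic** transcriptional classes are discovered and then
transferred to ordinary bulk samples through classifiers that either
tolerate (nearest-template prediction) or ignore (rank-based top-scoring
pairs) platform- and contamination-induced distortions.

The pipeline assumes log2-scale expression with one row per gene and
unique, opaque gene identifiers; probe-to-gene collapsing, normalization
across arrays and cross-species probe filtering are upstream concerns and
out of scope.

# Discovery

## Consensus factorization and the number of classes

Genes with across-sample standard deviation above `sd_threshold`
(default **0.8**, log2 units — the conventional cut separating
biologically variable genes from array noise) are retained and each
sample is standardized to mean 0, s.d. 1. Because the standardized matrix
has negative entries, it is made non-negative by *row splitting*: each
gene contributes a positive-part row and a negated-negative-part row.
This is the standard device for applying NMF to centered data; it doubles
the rows without changing which samples share structure.

For each candidate K (default 2–6) the matrix is factorized `n_runs`
times (default **50**) with multiplicative Kullback–Leibler updates from
uniform random starts. A run's sample partition is the dominant metagene
per sample; a run converges when the partition is unchanged for 40
consecutive iterations (cap 2,000). The **consensus matrix** is the
fraction of runs in which two samples co-cluster; hard labels come from
average-linkage hierarchical clustering of `1 − consensus`, and clustering
stability is the **cophenetic coefficient**, the correlation between the
dendrogram's cophenetic distances and `1 − consensus` itself. The chosen K
maximizes the cophenetic coefficient; an exactly block-diagonal consensus
gives 1.0.

## From clusters to a portable signature

Samples with negative silhouette width under the consensus distance are
dropped, so the supervised steps see only core representatives of each
class. Differential expression across classes uses a SAM-style moderated
statistic — between-class contrast over pooled within-class s.d. plus a
fudge factor `s0` (the median of the per-gene s.d.s, a common SAM default;
the grid-searched `s0` is deliberately not implemented) — with the null
obtained by label permutation. The q-value at each cut is the median
permutation exceedance count over the observed count, monotonized; the
default selection threshold is **FDR ≤ 0.005**, strict because the next
stage prefers a generous input pool it can shrink.

Nearest-shrunken-centroid (PAM) training soft-thresholds the standardized
centroid scores `d_ik` at Δ chosen by leave-one-out cross-validation over
a 30-point grid from 0 to max |d|. When several Δ achieve the minimal
error we keep the **smallest** one: gene selection here feeds a signature,
so among equally accurate models we prefer the one that retains every
gene compatible with that accuracy. (The alternative convention — largest
Δ, fewest genes — is the right call when the model itself is the product,
but it discards most true markers whenever classes are well separated.)
Uniform class priors are used throughout.

Two filters then produce the final signature. The **stromal filter**
removes genes whose estimated stroma-derived fraction of signal is
*strictly above* `threshold` (default **0.5**); a fraction of exactly 0.5
is kept, and genes missing from the stromal table are kept with a warning
(stroma-content estimates rarely cover the full gene space). The
**non-redundancy rule** assigns each remaining gene with a positive
shrunken score to its best class, but only when the margin over the
second-best positive score is at least `gap` (default **0.2**, in units
of the shrunken score); otherwise the gene is excluded. The result is a
set of disjoint per-class marker lists, and `filter_cascade_report()`
checks the bookkeeping of the funnel.

# Classification

## Nearest template prediction

Each class is a binary template over the union of signature genes; a
sample's distance to class c is `(1 − Pearson(x, t_c))/2 ∈ [0, 1]`,
computed on per-gene median-centered expression, and the sample is
tentatively assigned to the nearest template. The cosine-vs-correlation
choice in the original method is not fully specified; the Pearson form is
pinned here and tested for internal consistency.

Significance is by resampling. A subtle point drove the design: if the
null redraws only the *predicted* class's gene set, the p-value ignores
that the observed distance is a minimum over K classes and is biased low
(measured mean null p ≈ 0.12 on pure noise). The null used here redraws
the **whole template system** — `|union|` genes sampled from all measured
genes, partitioned into per-class blocks of the observed sizes — and
takes the minimum distance, replicating the decision rule. On pure-noise
data the resulting p-values are uniform (KS p ≈ 0.2 at 200 samples) and
essentially no sample survives the FDR gate. Benjamini–Hochberg
adjustment is applied across all samples of a run jointly, and samples
with FDR ≥ `threshold` (default **0.2**) are `UNASSIGNED`, as is any
sample with an exact distance tie.

## Multiclass top-scoring pairs

The k-TSP classifier votes on within-sample gene order only, so it is
invariant under any strictly increasing per-sample transform — the
property that makes it a single-sample, cross-platform rule.

*Gene filtering.* Cross-platform reproducibility is scored by integrative
correlation: within each dataset, gene–gene correlations of
rank-transformed expression; per gene, the Pearson correlation of its
correlation profiles (self excluded) between each dataset pair; the total
ICOR is the mean over pairs. Whether the outer correlation should itself
be rank-based is unstated in the sources; Pearson on the profiles is
adopted. The ICOR distribution is dichotomized by a two-component
Gaussian mixture (EM, via mclust, unequal variances) cut at the
equal-posterior crossing; genes in the upper component are kept.

*Pair search.* Candidates per class are the top 50 genes by rank-sum
separation (class vs rest). Comparisons are searched in a planned order —
priority classes first, then ascending candidate-pool size — and within
each comparison the k (default **4**) highest-Δ pairs are taken greedily,
where Δ = |P(X_i < X_j | class X) − P(X_i < X_j | class Y)| with
within-sample ties counting 0.5. The secondary score γ (absolute
between-class difference of mean within-sample rank gaps, the standard
k-TSP secondary statistic) breaks Δ ties, then lexicographic gene ids for
full determinism. Genes used by any selected pair are removed from all
subsequent searches, so all pairs are disjoint: k pairs × C(n, 2)
comparisons, 2k·C(n, 2) distinct genes (40 pairs / 80 genes for five
classes at k = 4).

*Voting.* Each evaluable pair votes within its comparison (pairs with
unmeasured genes are skipped). The sources count "votes / comparisons
involving the class", which with k pairs per comparison can exceed 1 if
votes are tallied per pair; here each comparison contributes its **vote
share** (fraction of its evaluable pairs voting for the class), and a
class's proportion is the mean share over its evaluable comparisons. This
reduces to the simple rule at k = 1, keeps proportions in [0, 1] and
preserves the ordering of any per-pair tally. The unique maximum wins;
ties among ≥ 3 classes leave the sample `UNASSIGNED`; a two-way tie is
resolved by the head-to-head comparison's vote share and left
`UNASSIGNED` if that is tied too.

`tsp_to_ntp_signatures()` reads each pair's orientation — the high gene
calls the class voted when it wins, the low gene calls the opponent — and
yields a reduced disjoint signature of k(n − 1) genes per class for
nearest-template use on platforms where absolute levels are comparable.

# Characterization statistics

Signature scores are `mean(up) − mean(down)` and receptor-activity scores
`(receptor + mean(ligands))/2`, both on per-gene median-centered log2
values; the centering cohort is always the input matrix. The receptor
weighting follows the literal reading of "averaging the receptor with its
ligands": the receptor counts as much as the whole ligand block. Sample
set enrichment ranks samples by a score and treats class memberships as
sets in the preranked weighted-KS engine (hit increments ∝ |value|^p,
default p = 1; misses 1/(N − N_hits)); significance permutes set
membership (the preranked analogue of gene permutation, default 1,000
permutations), NES divides ES by the mean |null ES| of matching sign, and
the FDR follows the standard pooled-NES procedure with BH on nominal
p-values available as a simpler flag. Mutational load is mutations per
megabase over a 30 Mb exome; copy-number load is the fraction of
profiled nucleotides in segments with |segment mean| **strictly** above
0.3 (1-based inclusive SEG coordinates; overlapping segments within a
sample are rejected as ambiguous). Cohen's kappa between two classifiers
drops `UNASSIGNED` pairs by default — concordance among confident calls —
with a flag to score `UNASSIGNED` as an ordinary class, since the
convention is not fixed in the field.

# The synthetic-data generator

`subtype_model()` emulates exactly the structure the pipeline assumes:
K latent subtypes (default 5) with disjoint marker blocks
(30 genes/class) shifted by `effect_size` (default 3, log2 units) in
their own class; a stromal program (40 genes at log2 level 4) mixed into
every sample as a convex combination
`(1 − f_s)·cancer + f_s·stroma` with `f_s ~ U(0, 0.3)`; 500 background
genes; Gaussian noise with s.d. 0.5. The mixing is applied directly on
the log2 scale — a linear approximation of what is really a
linear-space mixture — because it is the simplest structure that makes
the stromal filter meaningful; the per-gene stromal-fraction table
reports the expected share of signal of stromal origin under that
approximation. The defaults (200 samples, ~690 genes) keep a full
discovery run in seconds while leaving the signal-to-noise ratio (effect
3 vs noise 0.5) high enough that failure to recover the planted structure
indicates a defect, not bad luck.

What the generator does **not** emulate: count-level RNA-seq noise,
batch effects beyond monotone platform distortion, correlated marker
blocks, class-dependent stromal content, or partially overlapping
subtype programs. Passing the recovery tests therefore demonstrates
correctness of the machinery, not expected accuracy on real tumours,
where class separation is far weaker and assignment rates well below
100% are the norm.

`simulate_multiplatform()` applies per-platform strictly increasing
distortions (shift, positive scale, cubic term) plus noise, preserving
within-sample ranks in expectation — the regime ICOR and k-TSP are built
for. `simulate_segments()` tiles a scaled-down genome (default 3 Mb, 50
segments) and splits the boundary segment so the altered-nucleotide
fraction is exact; `simulate_mutation_counts()` is Poisson with mean
`rate_per_mb × exome_mb`.

# Numerical choices and degenerate inputs

* NMF updates add 1e−12 to denominators; runs are independent draws from
  one seeded stream, so results are reproducible from a single seed.
* SAM refuses fewer than 25 permutations (the FDR estimate is unstable);
  a constant gene scores exactly 0 and is never selected.
* PAM refuses single-sample classes (leave-one-out degenerates); with Δ
  beyond max |d| all genes are inactive and accuracy falls to the
  majority baseline.
* The EM dichotomization refuses < 20 values or zero variance, and falls
  back to the component-mean midpoint if the equal-posterior crossing
  cannot be bracketed.
* NTP requires ≥ 50% of each class's genes to be measured; a sample that
  is constant across the signature union has undefined correlation and is
  treated as uninformative (distance 0.5 to every class).
* Enrichment sets smaller than 2 or larger than N − 2 are skipped with a
  warning; `bh_fdr()` validates p ∈ [0, 1].
* All stochastic functions take explicit seeds; defaults are documented
  in the help pages.

# Problem sizes used in the checks

The shipped tests and the acceptance script run the full pipeline on the
default generator conditions (5 × 40 = 200 samples, ~690 genes, 50 NMF
restarts per K, 200 SAM permutations, 1,000 NTP resamples, 1,000
enrichment permutations where significance is asserted, 200 where only
calibration rates are estimated). These sizes were chosen so that the
whole suite completes in a few minutes on a single CPU while every
stochastic assertion retains comfortable margins.

# Known limitations

* Consensus NMF cost grows linearly in runs × iterations × matrix size;
  cohorts of thousands of samples will want fewer restarts or a subsample.
* The permutation FDR in the SAM step, like the original, can be
  anti-conservative when classes are strongly unbalanced.
* The ICOR mixture assumes two Gaussian components; a unimodal ICOR
  distribution (all genes equally reproducible) yields an arbitrary split
  and should be caught by inspecting the reported component means.
* The stromal filter is only as good as the per-gene stromal-fraction
  table; genes absent from the table pass the filter.
* No survival or outcome analysis is included by design.
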