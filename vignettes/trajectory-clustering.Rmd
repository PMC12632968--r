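---
title: "Temporal trajectory clustering and cluster switching: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal trajectory clustering and cluster switching: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajswitch)
```

## The problem

Developmental time-course RNA-seq asks how each gene's expression moves
across ordered stages (for example embryonic gonad, young adult and aged
ovary), and whether an experimental condition — here a comparison
condition such as IVF conception against naturally conceived controls —
reshapes those temporal trajectories. Differential expression at single
time points misses this: a gene can be indistinguishable at every stage
in isolation yet follow a different *shape* over time. `trajswitch`
clusters genes by trajectory shape in a reference condition and then
asks which genes abandon their cluster in the comparison condition.

## The pipeline

### Expression filter

Genes enter the analysis only if they are convincingly expressed:

1. **Prevalence**: CPM at or above `cpm_threshold` (default 1) in at
   least `max(ceiling(prevalence_fraction * n_samples),
   min_prevalent_samples)` samples — by default 20% of all samples and
   never fewer than 2.
2. **Stage detection**: a raw count above zero in at least one sample of
   *every* developmental stage, conditions pooled.

The two criteria are deliberately different in kind: prevalence uses the
depth-normalized CPM value, detection uses raw counts, so a gene
expressed only in one stage is removed even when it is highly expressed
there. Library sizes for CPM are always computed on the full input
matrix before filtering, so the threshold refers to each sample's true
sequencing depth rather than to whichever gene subset survived.

### Standardization

Filtered counts are converted to CPM and each gene is reduced to a
standardized trajectory. By default the pipeline standardizes
`log2(CPM + 1)` (`run_config(log_transform = TRUE)`): on the log scale,
sequencing noise is approximately additive and of comparable magnitude
at every expression level, so a gene's Z-scored trajectory reflects its
fold-change shape. Standardizing linear CPM is available
(`log_transform = FALSE`) but has a known pathology for strongly
modulated genes: the stage with the highest expression dominates both
the shape and the noise, so every strongly induced gene collapses
toward a "spike at its maximal stage" profile and within-cluster noise
becomes one-dimensional. With clearly separated trajectory groups this
inflates the relative WCSS gains beyond the elbow (splitting an
elongated cluster along its long axis removes up to $2/\pi \approx 64\%$
of that cluster's variance), which can push the 5% elbow rule past the
true cluster count no matter how little noise there is — the gains are
invariant to the overall noise scale. The log transform removes the
pathology at its source and is the default for that reason.

Z-scores use the sample standard deviation ($n-1$). Genes with zero
variance carry no trajectory information and are dropped and reported
rather than propagated as non-finite rows. Z-scoring pools the samples
of both conditions (`zscore_scope = "pooled"`) so that the two
conditions' profiles live on a single scale and can be compared against
shared centroids; per-condition scaling is available for sensitivity
analysis.

### Stage-mean profiles

For each condition, a gene's profile is the mean Z-score of its samples
at each stage, in declared stage order. Stage order is always an
explicit input — labels such as `E18.5` and `12wk` cannot be sorted
textually — and every stage must contain at least one sample of the
profiled condition.

### Clustering and the elbow rule

Profiles of the *reference* condition are clustered with k-means
(Lloyd's algorithm, squared Euclidean distance). The implementation is
deliberately self-contained so its semantics are exact and seeded:

* each restart draws `k` distinct profile rows uniformly at random as
  initial centers from a seeded generator (50 restarts, up to 1000
  iterations by default), and the restart with the lowest within-cluster
  sum of squares (WCSS) wins;
* nearest-centroid ties break toward the lowest centroid index;
* a cluster emptied during iteration is repaired by reseeding it with
  the point farthest from its current centroid, so returned models never
  contain empty clusters;
* every k in the sweep gets its own sub-seed derived by hashing
  `(seed, k)`, so widening the sweep range never perturbs other fits.

The sweep covers `k = 2..15` by default and records the WCSS curve. The
cluster count is chosen by the elbow rule: the smallest k for which
moving to k + 1 reduces WCSS by less than `gain_threshold` (default 5%)
of its current value. If every step gains at least the threshold, the
largest swept k is returned and flagged `"no-elbow"`; a WCSS curve that
*rises* beyond numerical tolerance is treated as an error signalling too
few restarts. The gain table is returned so the choice can be audited.
Cluster labels are made deterministic by sorting clusters on their
first-stage centroid value (ties by size), so repeated runs and plots
are comparable.

### Cluster switching

The comparison condition is *not* re-clustered. Its profiles are
projected onto the reference-trained centroids by nearest-centroid
assignment (ties to the lowest label). This makes "switching"
well-defined without any cluster-matching step: a gene switches when
its nearest reference centroid differs between the conditions' profiles.
The k × k transition table (reference clusters in rows, comparison
clusters in columns) is exactly the quantity an alluvial plot draws; the
off-diagonal genes are the switchers. Genes lacking a profile in either
condition (dropped as zero-variance) are excluded from the transition
universe and listed. Re-clustering the comparison condition
independently is a reasonable alternative design, but it requires
solving a cluster-correspondence problem and leaves switching defined
only up to that matching; projection was chosen as the default because
it keeps the comparison anchored to one trained model.

Gene lists from other analyses (for example per-stage differential
expression) can be intersected with `intersect_gene_sets()`, which
returns all disjoint Venn regions of two or three sets with counts and
members.

## Auxiliary assays

**Relative mtDNA copy number.** `ddct_ratio()` implements the
delta-delta-Ct method for mitochondrial-to-nuclear DNA ratios:
replicate Cts are averaged per sample and target, $\Delta Ct =
Ct_{mt} - Ct_{nuc}$, $\Delta\Delta Ct$ centers on the arithmetic mean
$\Delta Ct$ of the reference group, and the ratio is
$2^{-\Delta\Delta Ct}$. Arithmetic-mean centering of $\Delta Ct$ is
equivalent to geometric-mean centering of ratios, so the reference
group's geometric mean ratio is 1 by construction. When several
mitochondrial targets are assayed (such as ND1 and Cox3 against the 18S
rRNA gene) each is normalized separately and the per-sample mean is
additionally reported, since different targets can legitimately
disagree. Group comparisons use Welch's two-sample t-test, which does
not assume equal variances.

**Targeted bisulfite methylation.** `methylation_summary()` reports
per-CpG percent methylation, methylated / (methylated + unmethylated) ×
100, only where read coverage reaches `min_coverage` (default 10 reads,
a common floor for amplicon bisulfite data); under-covered CpGs are
flagged missing rather than treated as zero. Amplicon summaries are
coverage-weighted means over passing CpGs — deeper CpGs are better
estimates of the locus — and an amplicon with no passing CpG is
reported missing. Group means weight samples equally.

## The synthetic-data generator

`simulate_counts()` exists so that every stage of the pipeline can be
validated against known truth. It emulates a two-condition,
three-stage developmental design with negative-binomial counts:

* gene g in archetype a, condition c, stage t has mean
  $\mu = \exp(b_g + A \cdot \mathrm{arch}_{a(g,c)}[t]) \cdot s_j$, where
  $b_g \sim N(\log 100, 1)$ is the gene's baseline, $A$ is the
  `amplitude` (default 2 on the natural-log scale, i.e. up to ~5-fold
  swings per unit of archetype value), and $s_j$ is the sample's
  relative library size, drawn log-uniformly from
  `library_size_range`;
* counts are negative-binomial with dispersion 0.1 (variance
  $\mu + 0.1\mu^2$), the magnitude typical of bulk RNA-seq biological
  replicates; dispersion 0 gives Poisson counts;
* the default design plants nine archetypes × 200 genes in 3 stages
  with 6 samples per stage per condition, matching a bulk developmental
  study with 5–6 individuals per group (a 5-sample variant is used for
  the low-input germ-cell design);
* a fraction `switch_fraction` (default 10%) of genes use a different,
  randomly drawn archetype in the comparison condition — the planted
  cluster switchers.

The archetype library is nine unit-norm, zero-mean stage vectors at
evenly spaced angles in the plane spanned by a linear and a quadratic
stage contrast: monotone rise and fall, early and late onset,
transient peaks and dips. Evenly spaced angles maximize the minimum
pairwise separation between shapes; because the pipeline standardizes
log-scale expression, these log-scale shapes are exactly what the
clustering sees, up to a common scale and sampling noise.

What the generator does **not** emulate: litter or batch structure,
gene–gene correlation, expression-dependent dispersion trends,
single-cell dropout, or genes belonging to no archetype at all (in real
data a large background of weakly patterned genes inflates the residual
WCSS at every k and so makes relative gains smaller). Tests passing on
these simulations therefore demonstrate that the implementation
recovers structure it is designed to recover — not that any particular
real data set contains nine clusters.

`simulate_ct()` and `simulate_bisulfite()` provide the analogous known-
truth inputs for the two auxiliary assays: a planted $\Delta Ct$ shift
of `effect_log2` cycles (true ratio $2^{-\mathrm{effect}}$) with
Gaussian replicate noise, and binomial methylated counts at Poisson
coverage.

## Numerical and design choices

* **Determinism.** All stochastic steps flow from one integer seed;
  per-k sub-seeds come from an integer hash so results are independent
  of sweep order. Two runs with the same inputs and seed are
  bit-identical, and generators restore the caller's RNG state.
* **Tolerances.** Z-score invariants are enforced at 1e-10; centroids
  match their members' means to 1e-8; the WCSS curve may rise by at
  most a 1e-9 relative tolerance before `select_k()` refuses it.
* **Degenerate inputs.** k equal to the number of distinct profiles
  yields WCSS 0; k = 1 yields the total sum of squares; duplicate rows
  reduce the number of admissible k. Zero-variance genes, zero-coverage
  amplicons and zero library sizes are all reported by name rather than
  silently propagated.
* **Problem sizes.** The package's own validation clusters 1,800
  simulated genes (9 archetypes × 200) over 3 stages with a full
  k = 2–15 sweep at 50 restarts, repeated over 10 seeds per design —
  small enough to run routinely on a laptop, large enough that the
  planted structure dominates sampling noise.

## Known limitations

* The elbow rule is a heuristic. On curves with no flat region it
  returns the largest swept k with an explicit `"no-elbow"` flag rather
  than guessing; users should inspect the gain table.
* Projection-based switching inherits the reference clustering: genes
  near cluster boundaries can switch under resampling. The reported
  per-gene distances to both centroids let users gauge how decisive a
  switch is.
* CPM is the only normalization offered; compositional shifts between
  conditions (which TMM-style factors address) are out of scope.
* Stage-mean profiles weight all samples of a stage equally; litter or
  batch random effects are not modelled.
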