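---
title: "Methods: clonality testing, methylation deconvolution and molecular classification with sarcomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality testing, methylation deconvolution and molecular classification with sarcomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomix)
```

sarcomix implements the statistical toolkit used to characterize tumors
that contain two histologically distinct components — the motivating case
is pulmonary sarcomatoid carcinoma (PSC), where an epithelial and a
sarcomatoid component coexist in one tumor and are separated by
microdissection. This vignette is the package's own account of each
method: the model, its assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## Clonality index

**Model.** For two mutation catalogs sharing $M$ somatic mutations, each
shared mutation is assigned a background probability $p$ — the chance that
a random unrelated tumor carries it. Under the null of independent origin,
the chance of observing the mutation in *both* components is the binomial
term $P(X) = \binom{n}{k} p^k (1-p)^{n-k}$ with $n = k = 2$, i.e. $p^2$.
The clonality index pools the evidence:

$$\mathrm{CI} \;=\; -\log_{10} \prod_{m=1}^{M} P(X)_m
             \;=\; -2 \sum_{m=1}^{M} \log_{10} p_m .$$

A large CI means the shared mutations are collectively too improbable to
have arisen twice independently, supporting a common clonal origin. The
product is evaluated in log space; there is no underflow even for
$M = 10^4$ mutations with $p = 10^{-6}$ (CI $= 1.2 \times 10^5$).

**Background probability.** The reference definition of $p$ is a
cohort recurrence frequency with add-one smoothing,
$p = (c + 1)/(N + 1)$, where $N$ is the reference-cohort size and $c$
counts cohort samples carrying the mutation. When the identical variant
(same chromosome, position, ref and alt allele) recurs in the cohort the
count is hotspot-level; otherwise it falls back to gene-level recurrence
(samples with any mutation in the gene). Smoothing keeps $p > 0$ for
private mutations, which would otherwise make CI infinite. Mutation
identity is always the `(chrom, pos, ref, alt)` key; gene symbols are
annotation.

**Cutoff calibration.** The CI scale has no universal threshold, so the
cutoff is calibrated per cohort by resampling: positive-control pairs are
built by drawing, for every cohort sample, two independent random subsets
of 40%, 60% and 80% of its mutations ("in duplicate" — the two subsets of
one sample form a known-clonal pair); an equal number of unrelated sample
pairs serve as negative controls. All pairs' CIs are pooled and the
threshold maximizing Youden's $J$ (sensitivity + specificity − 1) is
taken, with candidate thresholds at the midpoints of the sorted observed
CIs and ties broken toward the larger threshold (favoring specificity).
The procedure is repeated 100 times; the median and the 2.5/97.5
percentiles summarize the cutoff. One cutoff is produced per cohort,
pooled across the three fractions; per-fraction calibration is a trivial
variation (call `calibrate_cutoff()` with a single fraction). A pair is
called clonal when its CI strictly exceeds the cutoff median.

Two properties of this design are worth knowing. First, on cohorts whose
catalogs share no identical variants, every negative-control CI is exactly
0, so calibrated cutoffs are always positive. Second, per-repeat cutoffs
are strongly discrete — each is half the minimum positive-control CI,
which lives on a lattice of $-2\log_{10}((c+1)/(N+1))$ sums — so
calibration medians can coincide across cohorts; this is expected, not a
seeding artifact.

```{r clonality-example}
cohort <- generate_reference_cohort(20, seed = 1)
cal <- calibrate_cutoff(cohort, repeats = 20, seed = 2)
cal

pair <- generate_paired_components(100, shared_fraction = 0.6, cohort,
                                   seed = 3)
ci <- pair_clonality(pair$a, pair$b, cohort)
ci
classify_relatedness(ci, cal)$call
```

## Leukocyte-fraction deconvolution

**Model.** Each methylation beta value in a tumor sample is assumed to be
a two-population mixture of leukocyte and pure-tumor signal:
$\beta_i = \beta_{iL}\,\pi + \beta_{iT}\,(1 - \pi)$, where $\pi$ is the
leukocyte fraction (LF). The model loci are the 2000 probes most
differentially methylated between leukocytes and normal lung, 1000 in each
direction (`select_lf_loci()`, ranking by difference of group means; the
mean was chosen over the median as the aggregation since the sources are
replicate reference profiles — this is configurable only by pre-averaging).
$\beta_{iL}$ is the mean across the leukocyte reference samples.
$\beta_{iT}$ is unobservable, so the tumor with the least evidence of
leukocyte methylation serves as a surrogate, operationalized per locus:
the minimum over tumors at leukocyte-high loci and the maximum at
leukocyte-low loci (`estimate_pure_tumor_reference()`; a whole-sample
alternative is available via `per_locus = FALSE`). Per locus,
$\pi_i = (\beta_i - \beta_{iT})/(\beta_{iL} - \beta_{iT})$, clipped to
$[0, 1]$; the sample's LF is the mode of a Gaussian kernel density
estimate of the $\pi_i$ (Silverman's rule bandwidth, argmax over the grid
$0, 0.001, \ldots, 1$, ties resolved to the smallest $\pi$ — the paper
trail specifies only "mode of kernel density estimate", so the kernel,
bandwidth, grid and tie-break are package decisions).

**Parameters.** `spread_threshold` (default 0.05) excludes loci whose
reference spread $|\beta_{iL} - \beta_{iT}|$ would make the division
unstable; `min_loci` (default 50) aborts estimation when too few loci
remain. Both are in beta units.

**A numerical caveat.** If the model loci include many weak-spread probes,
the per-locus $\pi_i$ at those loci are noisy, clipping piles mass at 0
and 1, and the KDE mode can lock onto a boundary instead of the true
fraction. In practice the 2000 loci are the top of a full array
(hundreds of thousands of candidates) and have spreads around 0.6 or
higher, where recovery is accurate to about 0.01 across the whole
$\pi \in [0, 1]$ grid at noise sd 0.03 — this is the condition the tests
and the acceptance script reproduce (2000 loci selected from a
20000-probe candidate pool). A second structural effect: because
$\beta_{iT}$ comes from the least-contaminated *observed* tumor, LF
estimates inherit a small downward bias of roughly the cohort's minimum
true fraction.

## Expression scores

**EMT score.** The score is the first principal component of the
expression of a 76-gene epithelial–mesenchymal transition signature
(an input file with per-gene epithelial/mesenchymal labels, not
hard-coded). The matrix is restricted to signature genes (at least 50%
must be present), log2(x+1)-transformed and gene-centered; PC1 is computed
without scaling, so each signature gene keeps its natural weight. Since a
principal component's sign is arbitrary, the score is oriented so that a
mesenchymal anchor gene (default `VIM`, falling back to the mean
mesenchymal loading) has nonnegative loading — higher scores mean more
mesenchymal. Scores are centered at zero by construction.

**Lymphocyte-infiltration score (ssGSEA).** A single-sample gene set
enrichment score of a predefined infiltration signature (an 18-gene set in
the motivating study). Genes are ranked by expression; walking down the
ranking, the score accumulates the difference between the weighted in-set
empirical CDF (weights $\mathrm{rank}^{0.75}$, the method's conventional
exponent) and the unweighted out-of-set CDF. Ties get average ranks and
tied order is broken by gene name, so the score is independent of input
gene order; being rank-based it is invariant under any strictly increasing
transform of the expression values. No cross-sample normalization is
applied — scores are comparable within one gene set across samples of one
matrix.

**Differential expression (Cyber-T).** A Bayesian-regularized t-test for
small groups: per gene and group, the log2(x+1) variance is shrunk toward
the mean variance of the `window` (default 101) genes nearest in average
log expression, with `prior_df` (default 10) pseudo-observations:
$\tilde s^2 = (\nu_0 s_0^2 + (n-1) s^2)/(\nu_0 + n - 2)$. The statistic is
a Welch t on the regularized variances; per-group degrees of freedom are
augmented to $\nu_0 + n - 2$ and combined by Welch–Satterthwaite (the
method's published description fixes the variance regularization but not a
two-sample df rule; this choice is validated empirically — null rejection
at $p < 0.05$ sits in $[0.03, 0.07]$). A gene is called differentially
expressed iff its *linear-scale* fold change is at least 2 in magnitude
(ratio $\ge 2$ or $\le 0.5$; the threshold is read as a magnitude) and
$p < 0.05$.

**Variable genes.** `top_variable_genes()` ranks genes by the median
absolute deviation of their log2(x+1) values and returns the top `n`
(default 2000), with ties broken lexicographically so selection is
deterministic.

## Methylation classification

**Probe filtering.** Six standard quality rules, applied in a fixed order
for reporting (the kept set is order-independent): detection $p > 0.01$ in
at least one sample; beadcount $< 3$ in at least 5% of samples; non-CpG
probe; SNP-containing probe; multi-mapping probe; X/Y chromosome (both
`"X"` and `"chrX"` dialects accepted). Filtering is idempotent and the
report names each removed probe's first violated rule.

**Differentially methylated probes.** A moderated t-test (empirical-Bayes
variance shrinkage across probes, via limma's standard formulation)
compares two groups on beta values; p-values are Benjamini–Hochberg
adjusted. A probe is a DMP iff adjusted $p \le 0.05$ *and* the absolute
difference of group **median** beta values is $\ge 0.3$. The test
statistic follows group means while the effect threshold follows medians —
both are reported, since the two deliberately differ.

**Cancer-specific hypermethylation.** Probes unmethylated in normals
(median beta $< 0.2$) and methylated in tumors (median beta $> 0.3$), both
strict inequalities.

**Clustering.** Agglomerative clustering with Euclidean distance and the
Ward minimum-variance criterion (`hclust` method `ward.D2`, the classical
Ward criterion on unsquared Euclidean distances; the tests verify its merge
sequence against a from-scratch ESS-increase agglomerator). The tree is cut
at `k` clusters and labels C1, C2, … are assigned by decreasing size —
the labels carry no biological identity; in the motivating study the
biology of C1–C3 came from external annotations.

**Cross-cohort probe selection.** For co-clustering with an external
cohort: probes significant between tumor and normal (BH-adjusted
$p \le 0.05$) with absolute *mean* beta difference $\ge 0.2$, reduced to
the 3000 most variable across tumors by MAD.

**Nearest-centroid subtyping.** Each sample's log2(x+1) profile, centered
by the cohort's gene medians, is Pearson-correlated with each subtype
centroid over the genes common to matrix and predictor (at least 10
required); the label is the argmax, ties resolving to the earliest
centroid column (flagged). The centroid matrix is also centered by its own
gene medians: published predictor centroids are centered values, and this
makes the identity case (a sample equal to a centroid) correlate at
exactly 1 while being a no-op for pre-centered predictors. Zero-variance
profiles get no label and are flagged.

**Methylation-subtype similarity.** Euclidean distance between each
sample's beta vector and per-subtype mean profiles over common probes;
smaller is more similar.

## Genomic summaries

* `compute_tmb()`: somatic SNVs + indels per megabase; the denominator is
  an explicit parameter (e.g. the capture design's target size) — no exome
  size is hard-coded.
* `partition_mutations()`: shared vs component-specific mutations by the
  `(chrom, pos, ref, alt)` key; `shared_pct` uses the union as denominator
  so that shared + specific proportions total 100%.
* `cnv_shared_percentage()`: same-state (gain∩gain + loss∩loss) covered
  length over the union CNV length, on 0-based half-open segments
  (merged on load, so splitting a segment into adjacent pieces changes
  nothing). Point mutations stay 1-based (MAF/VCF convention).
* `build_phylogenetic_tree()`: the two-leaf Newick tree
  `(E:bE,S:bS):t;` whose trunk is the shared and branches the specific
  nonsynonymous counts.
* `mutual_exclusivity_test()`: Monte Carlo test whose statistic is the
  number of samples mutated in ≥ 2 of the genes; the null independently
  permutes each gene's mutated-sample set, preserving per-gene counts but
  not per-sample burden (the simplest null consistent with the question;
  a per-sample-burden-preserving variant is a possible extension, and a
  pairwise co-occurrence statistic is available via `statistic =
  "pairwise"`). The add-one correction
  $p = (1 + \#\{\text{null} \le \text{obs}\})/(n_{perm} + 1)$ avoids
  $p = 0$.

## Synthetic data: what it emulates, and what it does not

Every generator plants a known ground truth and is bit-reproducible from
its seed (seeds never touch global RNG state; workflow stages derive
sub-seeds from one global seed via `derive_seed()`, recorded in the output
manifest). Ground truth is written to a JSON sidecar, never into the data
files, and the analysis stages operate on the data objects alone.

* `generate_reference_cohort()`: unrelated catalogs with long-tailed
  per-gene recurrence (a few frequent drivers, many rare — configuration,
  not a claim about PSC, whose frequency spectrum is not modeled) plus
  private passengers (Poisson, mean 100 per sample by default — an
  exome-scale burden consistent with several mutations per megabase over
  tens of megabases of coding sequence). Every mutation gets a globally
  unique position, so cohort catalogs are pairwise disjoint.
* `generate_paired_components()`: a mutation union of known size with a
  planted shared fraction; gene labels follow the cohort's empirical
  frequencies so shared mutations carry informative background
  probabilities.
* `generate_methylation_mixture()`: inverts the LF mixture model with
  truncated additive Gaussian noise on beta values.
* `generate_expression_with_structure()`: subtype centroids plus planted
  EMT shifts and infiltration levels with Gaussian noise on the log2
  scale (linear-scale output, floored at zero).
* `generate_cnv_pair()`: disjoint genome slots with a planted same-state
  overlap percentage, accurate to the slot granularity (1 point at the
  default 100 segments).
* `generate_methylation_cohort()`: planted sample clusters over
  cancer-specifically hypermethylated probes, plus probes deliberately
  violating each of the six filters.

What passing these tests shows is that the estimators recover parameters
under their own model assumptions at realistic noise levels. What they do
not show: robustness to array batch effects, probe cross-reactivity
beyond the filter flags, subclonal copy-number states, non-Gaussian
expression noise, or mutation-calling errors — real catalogs and matrices
inherit all of these from upstream pipelines that are out of scope here
(alignment, variant/CNV calling, array normalization, quantification).

## Workflows and problem sizes

`run_clonality_workflow()` and `run_classification_workflow()` wire the
stages end to end on simulated (or user-supplied) inputs, write one TSV or
JSON per stage plus a `manifest.json` with MD5 checksums and the derived
sub-seeds, and are byte-deterministic given a seed. Stage failures abort
with the stage name.

Default problem sizes throughout the test suite and the acceptance script
were chosen to exercise each method well inside a laptop-scale run: a
30-catalog reference cohort with 100 calibration repeats, 5000 probes with
100 planted DMPs, 2000 LF loci from a 20000-probe pool over the full
mixing grid, 100 samples over 4 expression subtypes, and 10^4
permutations for exclusivity tests.
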