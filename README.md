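# sarcomix

Statistical toolkit for the integrated molecular analysis of tumors with
two histologically distinct components, motivated by pulmonary sarcomatoid
carcinoma (PSC) — a rare lung cancer in which an epithelial and a
sarcoma-like component coexist within one tumor. The package is aimed at
cancer-genomics analysts who microdissect such tumors and need to answer,
reproducibly: *do the two components share a clonal origin? how
immune-infiltrated is each sample? how mesenchymal is each component? and
which molecular subgroup / conventional-lung-cancer subtype does each
tumor resemble?*

## What it computes

**Clonality index.** For the $M$ mutations shared by two components, each
with background probability $p$ in a reference cohort of unrelated tumors
($p = (c+1)/(N+1)$, hotspot- or gene-level recurrence with add-one
smoothing), the chance of a mutation appearing in both samples
independently is $P(X) = \binom{2}{2} p^2 (1-p)^0 = p^2$, and

$$\mathrm{CI} = -\log_{10} \prod_{m=1}^{M} P(X)_m .$$

A cutoff for calling a pair clonally related is calibrated by resampling:
positive controls are duplicate random subsets (40/60/80%) of single
cohort samples, negatives are unrelated sample pairs, and the
Youden-optimal threshold is recorded over 100 repeats (median and 95%
interval).

**Leukocyte fraction (LF).** Per methylation locus $i$, tumor beta values
follow the two-population mixture
$\beta_i = \beta_{iL}\pi + \beta_{iT}(1-\pi)$ over the 2000 loci that best
separate leukocyte from normal-lung methylation (1000 per direction);
solving per locus and taking the mode of a kernel density estimate of the
per-locus $\pi$ gives the sample's LF.

**Expression scores.** EMT score = oriented first principal component of a
76-gene epithelial–mesenchymal signature (higher = more mesenchymal);
lymphocyte infiltration = ssGSEA score of an 18-gene signature;
differential expression by Cyber-T (Bayesian-regularized t; called at
fold-change ≥ 2 and p < 0.05); top-2000 MAD gene selection.

**Methylation classification.** Six-rule probe filtering, moderated-t DMP
calling (adjusted p ≤ 0.05 and |Δ median β| ≥ 0.3), cancer-specific
hypermethylation probe selection (normal median < 0.2, tumor median >
0.3), Ward/Euclidean hierarchical clustering, nearest-centroid
transcriptional subtype prediction (maximum Pearson correlation with
predictor centroids), and Euclidean methylation-subtype similarity.

**Genomic summaries.** Tumor mutation burden per megabase, shared/specific
mutation partitioning, same-state CNV overlap percentage
(shared/union length), two-leaf Newick phylogenies (trunk = shared,
branches = specific nonsynonymous counts), and a Monte Carlo
mutual-exclusivity test.

**Synthetic data.** Seeded generators plant every quantity the analyses
estimate (shared fraction, LF, subtype labels, DMP set, CNV overlap), so
the whole pipeline is exercisable with known ground truth; planted
parameters live in a JSON sidecar that no analysis stage reads.

## Worked example

```r
library(sarcomix)

cohort <- generate_reference_cohort(20, seed = 1)   # unrelated WES catalogs
cal <- calibrate_cutoff(cohort, repeats = 20, seed = 2)
cal
#> CI cutoff calibration: median 10.212 (95% interval 8.170-13.275) over 20 repeats

pair <- generate_paired_components(100, shared_fraction = 0.6, cohort, seed = 3)
ci <- pair_clonality(pair$a, pair$b, cohort)
ci
#> Clonality index: CI = 122.191 over M = 60 shared mutations
ci$partition
#> Shared 60 / specific 20 + 20 mutations (60.0% shared)

classify_relatedness(ci, cal)$call
#> [1] "clonal"

build_phylogenetic_tree(ci$partition)
#> [1] "(E:15,S:11):41;"
```

Reading the numbers: the calibration says unrelated pairs from this cohort
essentially never exceed CI ≈ 10, while the simulated two-component pair —
built to share 60 of its 100 mutations — scores CI = 122, far above the
cutoff, so the two components are called clonally related; the Newick tree
summarizes its 41 shared and 15 + 11 component-specific nonsynonymous
mutations. `run_clonality_workflow()` and `run_classification_workflow()`
run these stages (plus probe filtering, clustering, LF, EMT, ssGSEA and
centroid prediction) end to end and write per-stage tables with a
checksummed manifest.

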