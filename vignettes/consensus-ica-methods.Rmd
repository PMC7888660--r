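---
title: "Methods: consensus ICA and iModulon extraction"
author: "imodulonr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus ICA and iModulon extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imodulonr)
```

## The model

A centered expression compendium **X** (genes x samples, log scale) is
decomposed as

$$\mathbf{X} = \mathbf{S}\,\mathbf{A}$$

where each column of **S** is an *independent component*: a gene-weighting
vector representing one co-regulated transcriptional signal, and each row of
**A** holds that signal's condition-dependent *activity* across samples.
The biological reading is that a handful of regulators independently
modulate overlapping sets of genes; ICA separates those signals because
regulatory gene weightings are sparse and heavy-tailed (strongly
non-Gaussian across genes), while unstructured noise is not. The
significantly weighted genes of one component form an **iModulon** — an
independently modulated gene set, the data-driven counterpart of a regulon.

Assumptions worth stating explicitly:

* activities of distinct components are (approximately) linearly
  independent across the sampled conditions — two regulators perturbed only
  in lock-step are unidentifiable and will fuse into one component;
* expression is treated as linear in log space; saturation and
  interaction effects are folded into the residual;
* each dataset has a designated reference condition, and profiles are
  compared as log fold changes against that reference.

## Preprocessing

Datasets pass four steps, in order:

1. **Profile QC** — drop samples with more than 300 missing entries
   (strictly greater; the bound is the public-compendium convention).
2. **Gene QC** — drop genes with any remaining missing value.
3. **Replicate QC** — within each replicate group, drop a profile whose
   *maximum* Pearson correlation with any other member falls below 0.2.
   Max-pairwise is deliberately the most permissive reading: a profile is
   kept as soon as it agrees with one mate, so only genuinely isolated
   profiles are lost. Singleton groups are untouched.
4. **Centering and concatenation** — each gene's mean over the dataset's
   reference samples is subtracted from every sample of that dataset; the
   centered datasets, restricted to their common genes (sorted
   lexicographically for platform-independent order), are column-bound with
   no further normalization. Centering removes any per-gene constant
   dataset offset *exactly*, which is why no explicit batch correction is
   applied — or needed — for additive gene-level batch structure.

An optional outlier flagger (average-linkage clustering on correlation
distance, singleton branches flagged) stands in for manual curation of
aberrant profiles; it is off by default and only flags, never removes.

## Consensus decomposition

Single ICA runs are stochastic: the fixed-point algorithm converges to
different local optima from different starts. The pipeline therefore
estimates components in three nested layers:

1. **Dimension**: the number of components per run is the smallest number
   of principal components explaining `variance_target` of the variance
   (default 0.99; 0.95 is the pragmatic choice for very large compendia,
   and lower values are appropriate when noise occupies a visible share of
   the spectrum).
2. **Ensemble**: FastICA (logcosh contrast, symmetric decorrelation,
   convergence tolerance 1e-6, default 100 restarts) is run from seeded
   random starts; every run's components are pooled. A run that fails to
   converge is retried once with a fresh derived seed, then skipped with a
   warning.
3. **Clustering**: pooled components are clustered with DBSCAN on the
   distance $d(x, y) = 1 - |\rho_{x,y}|$ (absolute Pearson correlation of
   gene weightings), with `eps = 0.1` and a minimum cluster seed size of
   50. The seed size is calibrated to 100 restarts — a component must recur
   in at least half the runs — and should be scaled proportionally when
   `n_runs` changes (the package's tests use `n_runs = 20`,
   `min_members = 10`). Each cluster becomes one robust component: members
   are sign-aligned to the first member, averaged, re-normalized.
4. **Repetition consensus**: the whole ensemble-and-cluster procedure is
   repeated (default 10 times) with independent derived seeds, and a
   component is kept only if every repetition contains a centroid with
   $|\rho| \ge 0.7$ against the reference centroid from the first
   repetition. The 0.7 match threshold sits well above the within-cluster
   similarity floor implied by `eps = 0.1` and is configurable. Using the
   first repetition as reference means a component that the first
   repetition happened to miss is dropped; with the default ten
   repetitions this is the conservative direction.

Two numerical conventions make components comparable across runs,
datasets and seeds: every **S** column has unit L2 norm, and its
largest-magnitude entry is positive. Both are arbitrary but deterministic;
all similarity computations use $|\rho|$ and are invariant to them.

FastICA estimates sources on gene-mean-centered mixtures, which leaves the
raw centroids a rank-one offset away from the column space of **X**. A
single alternating least-squares refit (`A = pinv(S) X`, then
`S = X pinv(A)`) returns **S** to that space, making the reconstruction
`X = S A` exact on noiseless data while leaving component directions
essentially unchanged. Activities are always recomputed as
`A = pinv(S) X` (Moore-Penrose via SVD) rather than averaged across runs:
the projection is exact for in-span data and well-defined even for
rank-deficient **S** (a condition-number warning is emitted).

## iModulon extraction

Gene weightings of a component are mostly near-Gaussian background plus a
heavy tail of genuinely regulated genes. Extraction iteratively removes the
gene with the largest absolute weight (ties broken lexicographically by
gene id) and recomputes the D'Agostino $K^2$ omnibus normality statistic
($Z_1(\text{skewness})^2 + Z_2(\text{kurtosis})^2$) on the remainder; the
first time $K^2$ falls below the cutoff — including before any removal —
the removed genes are the iModulon. The reported threshold is the smallest
absolute weight among members, so "member" coincides with "weight strictly
above threshold" up to ties at the boundary. Removal also stops if fewer
than 9 genes would remain ($K^2$'s approximations need 9) or if the
remainder has zero variance (exact zeros of a sparse weighting).

Two properties of $K^2$ matter operationally:

* it **scales with the number of genes** — both z-transforms saturate at a
  ceiling that grows with $n$, so a cutoff meaningful for a 4000-gene
  compendium is unreachable for a 300-gene toy matrix. The standard grid
  (below) presumes compendium-sized universes;
* extraction is **monotone in the cutoff**: a higher cutoff always yields
  a subset of a lower cutoff's iModulon (first-crossing argument), which
  makes the cutoff sweep well-behaved.

The cutoff is chosen against a reference TRN: each component is first
linked to the regulator whose regulon is most significantly enriched
(one-sided Fisher's exact test, Benjamini-Hochberg FDR < 1e-5) in its
top 20 genes by absolute weight; the preliminary link is computed once, not
per cutoff. Then the cutoff sweeps 200 to 1000 in steps of 50 (17 values)
and the value maximizing the mean F1-score between iModulons and their
linked regulons wins, ties resolving to the smallest cutoff. Without a
usable TRN the pipeline falls back to the grid midpoint (550) with a
warning, so TRN-free organisms still run.

## Characterization

Every iModulon is tested against regulons (FDR < 1e-5) and GO/prophage
sets (FDR < 0.01) with the one-sided Fisher's exact test; the BH family is
all component x annotation tests of a screen, a single coherent family per
annotation type. Categories follow a fixed priority: **Regulatory** (a
regulon passes; named for the lowest-q regulator), else **Genomic** (an
optional genotype table links the genes to a known alteration at overlap
coefficient >= 0.5 — an explicit automated proxy for what is usually manual
curation, off unless a table is supplied), else **Functional** (a GO or
prophage set passes), else **Uncharacterized**. Naming ties are broken
lexicographically and logged for curation.

## Comparing structures across datasets

Components of different datasets are compared on their shared genes by
$|\rho|$. For each dataset pair, a component's best hit is its
max-similarity partner; an edge of the **reciprocal best hit (RBH) graph**
exists only if the best hits are mutual and the similarity is at least 0.3
(the prune threshold mirrors the observation that unrelated components of
the same dataset rarely exceed ~0.27). Connected clusters of the pruned
graph are tiered by dataset span: *highly-reproducible* (one node from
every dataset), *moderately-reproducible* (more than half but not all),
*complex* (some dataset contributes two or more nodes), else
*dataset-specific*. Gene-set overlap is quantified by the
Szymkiewicz-Simpson coefficient $|A \cap B| / \min(|A|, |B|)$.

When one dataset's conditions co-activate two regulators, ICA of that
dataset fuses them into one component. `fit_linear_combination()`
diagnoses this: the ten candidate components (of another dataset) with the
highest $|\rho|$ to the target are selected and the target is regressed on
them by OLS with intercept (the intercept is retained because weightings
are not exactly zero-mean; it is configurable).

## Activities of contrasts and reproducibility

For two mean profiles centered to the same reference,
$\Delta A = \mathrm{pinv}(\mathbf{S})\,\Delta X$ and the per-component
explained variance is

$$EV_k = \frac{\sum (\Delta X)^2 - \sum (\Delta X - S_k \Delta A_k)^2}{\sum (\Delta X)^2}.$$

$EV_k$ may be negative when a component misfits a contrast; negative values
are reported raw because clipping would hide the misfit. The joint EV over
all components equals $1 - \lVert\Delta X - S\,\Delta A\rVert^2 /
\lVert\Delta X\rVert^2$ and reaches 1 exactly for in-span contrasts.

Replicate reproducibility of activities is summarized per component as the
mean within-replicate-group standard deviation normalized by the
component's activity range (normalizing by the overall SD is available as
an option; range was chosen as the more conservative denominator for
block-designed activities). Replicate groups are taken within datasets
only, since activities are relative to dataset-specific references and not
comparable across datasets. Components tracking biology score low;
components absorbing noise score high — the package's tests verify that an
injected pure-noise weighting ranks highest.

## The synthetic compendium generator

Because full-compendium reanalysis needs multi-hundred-sample public
downloads and hours of stochastic computation, the package validates every
stage against generated data with planted structure:

* **Gene weightings**: each planted component has 10-80 member genes
  (disjoint by default) with log-normal magnitudes (`sdlog = 0.5`) and
  random signs; columns are unit-normalized. This reproduces the sparse,
  heavy-tailed, two-sided shape of real weighting histograms.
* **Activities**: an integer condition design (entries -2..2, reference
  condition all-zero, every component active somewhere) times a
  per-component amplitude (`activity_scale`, default 5 log2 units, with a
  dataset-specific 0.7-1.3 multiplier). Replicates within a condition are
  exactly equal, so replicate dispersion in rendered data is entirely
  render noise and the replicate-RSD statistics have closed-form
  expectations. Designs are drawn per dataset with rejection so that
  pairwise activity correlations stay below 0.3 — the generator plants
  *independently* modulated signals, which is precisely ICA's
  identifiability condition. Two scenario switches break this on purpose:
  `correlate_pair` forces two components' activities into near lock-step
  (correlation >= 0.95) in one dataset, emulating a merged-regulon
  situation, and `inactive` silences components to create dataset-specific
  structure.
* **Baseline and noise**: rendered values are
  `baseline + S A + batch + noise`, with a per-gene baseline
  (N(8, 2) log2 units, shared across datasets) giving profiles the
  gene-intrinsic expression levels that make replicate-correlation QC on
  uncentered data informative, a per-dataset per-gene constant batch
  offset, and i.i.d. Gaussian noise (default SD 0.05, i.e. 1% of the
  default activity scale). Reference centering removes baseline and batch
  exactly. Real compendia publish no explicit noise model, so these
  defaults are this package's own calibration.
* **TRN**: one regulon per planted component, with seeded per-gene dropout
  and a fixed count of spurious genes, so enrichment and cutoff
  optimization are exercised against a realistically imperfect annotation.

What the generator does **not** emulate: probe-level microarray physics,
count noise and library-size effects of RNA-seq, correlated
(non-independent) measurement noise, condition-dependent variance, and
regulon overlap structure beyond the planted sets. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not performance on any particular real compendium.

## Problem sizes and determinism

The test suite and the acceptance script run the full stack on
1000-gene x 120-sample compendia with 8 planted components, 20 FastICA
restarts, and 5 consensus repetitions (with `min_members = 10`, keeping the
half-of-restarts ratio of the 100-restart default), plus smaller fixtures
for unit-level checks — sizes chosen so the whole validation cycle stays
interactive while every stage runs at full fidelity. All stochastic stages
draw their seeds from one master seed through a single derivation helper,
so every result in the package is a pure function of (inputs, parameters,
master seed); the pipeline writes an md5 manifest and reruns reproduce it
bit-for-bit.

## Known limitations

* ICA cannot separate components whose activities are collinear in the
  sampled conditions; such components appear merged (the package detects
  this cross-dataset via `fit_linear_combination()`, but cannot resolve it
  within one dataset).
* The $K^2$ cutoff grid (200-1000) presumes a compendium-sized gene
  universe; for small universes the statistic saturates below the grid and
  extraction returns empty sets. Use a proportionally smaller cutoff, or
  more genes.
* The repetition consensus anchors on the first repetition's centroids.
* Enrichment treats annotations as flat gene sets; GO ancestor propagation
  is not performed.
* Activities are relative to each dataset's reference condition and must
  not be compared across datasets.
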