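# imodulonr

Consensus independent component analysis of bulk transcriptomic compendia,
and extraction of **iModulons** — independently modulated gene sets, the
data-driven counterpart of regulons.

## The problem

A transcriptomic compendium — hundreds of expression profiles of one
organism across many conditions, often pooled from several studies and
platforms — mixes the signals of all active transcriptional regulators.
`imodulonr` unmixes them. It models a centered log-scale expression matrix
as

```
X = S · A
```

where each column of `S` is an independent component (a sparse,
heavy-tailed gene-weighting vector representing one co-regulated signal)
and each row of `A` holds that signal's activity across samples. The
significantly weighted genes of a component form an iModulon; comparing a
component's iModulon with known regulons, and its activities with the
experimental design, turns an unsupervised factorization into testable
regulatory biology.

The package is aimed at computational biologists assembling or reanalyzing
microbial (or other bulk) expression compendia who want the whole
analytical chain — QC, centering, decomposition, gene-set extraction,
annotation, cross-dataset comparison — reproducible from one seed.

## What the package does

* **Preprocessing** — missing-value QC for profiles (> 300 empty values)
  and genes (any empty value), replicate-correlation QC (Pearson < 0.2),
  gene-universe intersection across platforms, reference-condition
  centering, concatenation without further normalization.
* **Consensus ICA** — PCA-based dimension selection (99% variance by
  default), multi-restart FastICA (100 restarts, tolerance 1e-6), DBSCAN
  clustering of pooled components on the distance `1 − |ρ|` (eps 0.1,
  minimum cluster seed 50), and a 10-fold repetition consensus that keeps
  only components recurring in every repetition. Activities are recovered
  by pseudoinverse projection, `A = pinv(S)·X`.
* **iModulon extraction** — iterative removal of the largest-|weight| gene
  against the D'Agostino K² normality statistic until it drops below a
  cutoff; the cutoff is optimized (grid 200–1000, step 50) by F1-score
  against a reference transcriptional regulatory network (TRN).
* **Characterization** — one-sided Fisher's exact enrichment against
  regulons (FDR < 1e-5) and GO/prophage sets (FDR < 0.01), with
  Regulatory / Genomic / Functional / Uncharacterized categories.
* **Cross-dataset comparison** — reciprocal-best-hit graphs over `|ρ|`
  similarities (pruned at 0.3), reproducibility tiers for the connected
  clusters, Szymkiewicz–Simpson overlap coefficients, and a
  linear-combination regression that explains a merged component of one
  dataset by components of another.
* **Activity inference** — projection of expression contrasts
  (`ΔA = pinv(S)·ΔX`), per-component explained variance, and
  replicate-reproducibility summaries of activities.
* **Synthetic compendia** — a seeded generator planting known components,
  condition-block activities, baselines, batch offsets, noise and an
  imperfect TRN, so every stage is validated against ground truth.

## A worked example

Plant an 8-component truth, render two noisy 60-sample datasets, and run
the chain end-to-end:

```r
library(imodulonr)

gt <- make_ground_truth(n_genes = 1000, n_components = 8,
                        genes_per_component = c(10, 80),
                        n_conditions = 20, replicates = 3, seed = 1)
r1 <- render_dataset(gt, "rnaseq1", noise_sd = 0.05, seed = 2)
r2 <- render_dataset(r1$ground_truth, "rnaseq2", noise_sd = 0.05, seed = 3)

x1 <- center_to_reference(r1$x, r1$meta)
x2 <- center_to_reference(r2$x, r2$meta)
comp <- concatenate_datasets(list(x1, x2), list(r1$meta, r2$meta))
comp$x
#> ExpressionMatrix 'combined': 1000 genes x 120 samples (centered)

dec <- run_robust_ica(comp$x, n_runs = 20, n_repetitions = 5,
                      min_members = 10, seed = 4)
dec
#> Decomposition of 'combined': 1000 genes x 8 components x 120 samples

trn <- make_trn(r2$ground_truth, dropout = 0.1, spurious_per_regulon = 5,
                seed = 5)
opt <- optimize_cutoff(dec$S, trn)
opt$cutoff
#> [1] 200
ims <- extract_all_imodulons(dec, opt$cutoff)
ims[[1]]
#> IModulon IC01: 52 genes, |weight| threshold 0.02793 (K2 cutoff 200)

res <- enrich_imodulons(ims, trn, universe_size = 1000)
head(res[, c("component_id", "set_id", "overlap", "set_size", "q", "f1")], 3)
#>   component_id set_id overlap set_size            q        f1
#> 1         IC07    R_1      71       76 2.944135e-93 0.9281046
#> 2         IC03    R_8      57       62 1.438470e-81 0.9344262
#> 3         IC02    R_7      58       63 5.246478e-76 0.8854962
```

Every recovered component matches a planted one (the decomposition found
all 8, median `|ρ|` against the planted weightings 0.9997), each top
enrichment pairs a component with the regulon that generated it despite the
TRN's 10% dropout and 5 spurious genes per regulon, and the extracted
iModulons reproduce the planted regulons at median F1 = 1. The same
stages are scriptable through `run_pipeline()` (see
`inst/scripts/imodulon-pipeline.R` for a shell wrapper) with a YAML/JSON
config and an md5-checksummed artifact manifest.

## Documentation

The methods vignette (`vignettes/consensus-ica-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, the synthetic generator's scope, numerical conventions, and
known limitations.
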