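## Synthetic compendium generator with planted regulatory structure.
##
## Emulates the statistical shape of a multi-dataset expression compendium:
## a sparse gene-weighting matrix S with heavy-tailed nonzero entries,
## condition-block activities A with exact replicates and an all-zero
## reference condition, dataset-specific Gaussian noise and per-gene batch
## offsets, and partially shared gene universes. Every downstream stage is
## validated against this known ground truth.

#' Create a ground truth with planted components
#'
#' Plants `n_components` gene modules into a gene universe. Each module's
#' nonzero weightings have log-normal magnitudes with random (Rademacher)
#' signs — matching the heavy-tailed weighting histograms seen in real
#' compendium decompositions — and every column of the planted `true_S` is
#' scaled to unit L2 norm. Activities follow an integer condition design
#' (identical within a condition, zero in the reference condition), so
#' replicate dispersion in rendered data comes only from render noise.
#'
#' @param n_genes size of the global gene universe.
#' @param n_components number of planted components (>= 2).
#' @param genes_per_component integer range `c(min, max)` of planted module
#'   sizes; a single number plants equal-sized modules.
#' @param n_conditions number of conditions per rendered dataset, including
#'   the reference condition.
#' @param replicates replicates per condition (>= 2).
#' @param activity_scale amplitude of condition activities (log-expression
#'   units per design unit).
#' @param seed master seed; identical seeds reproduce the ground truth
#'   bit-for-bit.
#' @param disjoint if `TRUE` (default) planted modules are pairwise disjoint.
#' @return an object of class `GroundTruth` with fields `true_S`,
#'   `regulon_map`, `true_A_by_dataset` (filled by [render_dataset()]),
#'   `gene_universe_by_dataset`, `noise_sd`, `batch_offsets`, `design`
#'   parameters and `master_seed`.
#' @export
make_ground_truth <- function(n_genes, n_components,
                              genes_per_component = c(10L, 80L),
                              n_conditions = 10L, replicates = 3L,
                              activity_scale = 5, seed = 1L,
                              disjoint = TRUE) {
  if (n_genes < 1 || n_components < 2 || n_conditions < 2) {
    stop("non-positive or degenerate dimensions: need n_genes >= 1, ",
         "n_components >= 2, n_conditions >= 2")
  }
  if (replicates < 2) stop("need replicates >= 2")
  gpc <- as.integer(genes_per_component)
  if (length(gpc) == 1L) gpc <- c(gpc, gpc)
  if (gpc[1] < 1 || gpc[2] < gpc[1]) stop("invalid genes_per_component range")
  if (disjoint && gpc[2] * n_components > n_genes) {
    stop("sizing error: ", n_components, " disjoint components of up to ",
         gpc[2], " genes cannot fit in ", n_genes, " genes")
  }

  genes <- sprintf("g%04d", seq_len(n_genes))
  with_seed(seed, {
    sizes <- sample(seq(gpc[1], gpc[2]), n_components, replace = TRUE)
    true_S <- matrix(0, n_genes, n_components,
                     dimnames = list(genes, sprintf("C%02d", seq_len(n_components))))
    pool <- seq_len(n_genes)
    regulon_map <- vector("list", n_components)
    names(regulon_map) <- colnames(true_S)
    for (k in seq_len(n_components)) {
      idx <- sample(pool, sizes[k])
      if (disjoint) pool <- setdiff(pool, idx)
      mags <- stats::rlnorm(sizes[k], meanlog = 0, sdlog = 0.5)
      signs <- sample(c(-1, 1), sizes[k], replace = TRUE)
      true_S[idx, k] <- mags * signs
      regulon_map[[k]] <- sort(genes[idx])
    }
    true_S <- unit_norm_columns(true_S)
    true_S <- fix_column_signs(true_S)

    # per-gene baseline log2 expression, shared across datasets: real
    # compendia have gene-intrinsic expression levels, which is what makes
    # replicate-correlation QC on uncentered profiles informative;
    # reference centering removes the baseline exactly
    baseline <- stats::setNames(stats::rnorm(n_genes, mean = 8, sd = 2),
                                genes)
  })

  structure(
    list(true_S = true_S,
         regulon_map = regulon_map,
         baseline = baseline,
         activity_scale = activity_scale,
         n_conditions = as.integer(n_conditions),
         replicates = as.integer(replicates),
         true_A_by_dataset = list(),
         gene_universe_by_dataset = list(),
         noise_sd = numeric(0),
         batch_offsets = list(),
         provenance = list(),
         master_seed = as.integer(seed)),
    class = "GroundTruth"
  )
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d genes, %d planted components, %d dataset(s) rendered\n",
              nrow(x$true_S), ncol(x$true_S), length(x$true_A_by_dataset)))
  invisible(x)
}

#' Render one dataset from a ground truth
#'
#' Draws a dataset-specific integer condition design (reference condition
#' all-zero, every component active in at least one condition) scaled by
#' per-component amplitudes — so activities are condition blocks, exactly
#' replicated within conditions and independent across datasets — restricts
#' the gene universe to a seeded random subset, and emits
#' `X = baseline + S * A + batch + noise` as an *uncentered* expression
#' matrix — centering on the reference condition (which removes both the
#' per-gene baseline and the batch offset exactly) is the preprocessing
#' stage's job.
#'
#' @param gt a [make_ground_truth()] object.
#' @param dataset_id unique dataset identifier.
#' @param noise_sd standard deviation of i.i.d. Gaussian measurement noise.
#' @param gene_subset_fraction fraction (0, 1] of the global gene universe
#'   measured by this dataset (seeded sampling without replacement).
#' @param batch_shift_sd standard deviation of the per-gene constant batch
#'   offset for this dataset.
#' @param seed seed for this dataset's activities, subset, offsets and noise.
#' @param correlate_pair optional integer pair `c(k1, k2)`: component `k2`'s
#'   activities are made nearly identical to `k1`'s in this dataset
#'   (correlation >= 0.95), emulating a merged-regulon scenario.
#' @param inactive optional integer indices of components whose activities
#'   are zero throughout this dataset, making them dataset-specific to the
#'   other rendered datasets.
#' @param max_activity_cor target bound on the pairwise correlation between
#'   planted condition designs (default 0.3); rows are redrawn (up to 50
#'   tries, keeping the best) until the bound holds, so planted activities
#'   are approximately independent, as an ICA decomposition assumes.
#' @return list with elements `x` (ExpressionMatrix), `meta` (SampleTable)
#'   and `ground_truth` (the input with this dataset's truth recorded).
#' @export
render_dataset <- function(gt, dataset_id, noise_sd = 0.05,
                           gene_subset_fraction = 1, batch_shift_sd = 0,
                           seed = 1L, correlate_pair = NULL,
                           inactive = integer(0), max_activity_cor = 0.3) {
  stopifnot(inherits(gt, "GroundTruth"))
  if (dataset_id %in% names(gt$true_A_by_dataset)) {
    stop("dataset_id '", dataset_id, "' already rendered")
  }
  if (gene_subset_fraction <= 0 || gene_subset_fraction > 1) {
    stop("gene_subset_fraction must be in (0, 1]")
  }
  n_genes <- nrow(gt$true_S)
  k <- ncol(gt$true_S)
  n_cond <- gt$n_conditions
  reps <- gt$replicates
  n_samples <- n_cond * reps

  cond_names <- sprintf("cond%02d", seq_len(n_cond))
  with_seed(seed, {
    # gene subset first: a plain seeded draw, independently re-enumerable
    n_keep <- round(gene_subset_fraction * n_genes)
    keep <- sort(sample.int(n_genes, n_keep))

    # dataset-specific integer condition design: reference condition
    # (first) all zero, every component active in >= 1 condition. Rows are
    # drawn greedily with rejection so pairwise activity correlations stay
    # below max_activity_cor — the generator plants *independently*
    # modulated signals, which is the separability assumption of ICA
    design <- matrix(0L, k, n_cond,
                     dimnames = list(colnames(gt$true_S), cond_names))
    for (j in seq_len(k)) {
      best <- NULL
      best_c <- Inf
      for (try in seq_len(50L)) {
        eff <- sample(c(-2L, -1L, 0L, 1L, 2L), n_cond - 1L, replace = TRUE)
        if (!any(eff != 0L)) next
        if (j == 1L) { best <- eff; break }
        cc <- max(abs(stats::cor(c(0L, eff),
                                 t(design[seq_len(j - 1L), , drop = FALSE]))))
        if (cc < best_c) { best_c <- cc; best <- eff }
        if (cc < max_activity_cor) break
      }
      design[j, -1L] <- best
    }
    if (length(inactive)) design[inactive, ] <- 0L
    amp <- gt$activity_scale * stats::runif(k, 0.7, 1.3)
    A_cond <- design * amp         # components x conditions
    if (!is.null(correlate_pair)) {
      stopifnot(length(correlate_pair) == 2L)
      k1 <- correlate_pair[1]; k2 <- correlate_pair[2]
      # near-duplicate activity pattern with tiny independent perturbation
      A_cond[k2, ] <- A_cond[k1, ] +
        stats::rnorm(n_cond, sd = 0.05 * gt$activity_scale)
      A_cond[k2, 1L] <- 0          # reference stays zero
    }
    A <- A_cond[, rep(seq_len(n_cond), each = reps), drop = FALSE]
    colnames(A) <- paste0(rep(cond_names, each = reps),
                          "_r", rep(seq_len(reps), n_cond))

    batch <- stats::rnorm(n_keep, sd = batch_shift_sd)
    noise <- matrix(stats::rnorm(n_keep * n_samples, sd = noise_sd),
                    n_keep, n_samples)
    X <- gt$baseline[keep] + gt$true_S[keep, , drop = FALSE] %*% A +
      batch + noise
  })
  rownames(X) <- rownames(gt$true_S)[keep]
  colnames(X) <- colnames(A)

  lost <- vapply(seq_len(k), function(j) {
    all(which(gt$true_S[, j] != 0) %in% setdiff(seq_len(n_genes), keep))
  }, logical(1))
  prov <- list(seed = as.integer(seed), noise_sd = noise_sd,
               batch_shift_sd = batch_shift_sd,
               gene_subset_fraction = gene_subset_fraction,
               lost_components = colnames(gt$true_S)[lost])
  if (any(lost)) {
    warning("gene subset removed all planted genes of component(s): ",
            paste(colnames(gt$true_S)[lost], collapse = ", "))
  }

  meta <- sample_table(
    sample_id = colnames(A),
    dataset_id = dataset_id,
    condition_id = rep(cond_names, each = reps),
    replicate_group = rep(cond_names, each = reps),
    is_reference = rep(seq_len(n_cond) == 1L, each = reps)
  )

  gt$true_A_by_dataset[[dataset_id]] <- A
  gt$gene_universe_by_dataset[[dataset_id]] <- rownames(X)
  gt$noise_sd[dataset_id] <- noise_sd
  gt$batch_offsets[[dataset_id]] <- stats::setNames(batch, rownames(X))
  gt$provenance[[dataset_id]] <- prov

  list(x = expression_matrix(X, dataset_id = dataset_id, centered = FALSE),
       meta = meta,
       ground_truth = gt)
}

#' Derive a noisy regulatory network from planted modules
#'
#' Builds one regulon per planted component: the planted gene set minus a
#' seeded per-gene dropout, plus spurious genes sampled from outside the
#' planted set. Regulator names are stable (`R_k` for component `k`).
#'
#' @param gt a [make_ground_truth()] object.
#' @param dropout per-gene probability (in `[0, 1)`) that a planted gene is
#'   missing from its regulon annotation.
#' @param spurious_per_regulon number of false-positive genes added per
#'   regulon.
#' @param seed seed for the dropout and spurious draws.
#' @return named list of regulons (annotation_type `"regulon"`). A dropout
#'   draw that would empty a regulon is redrawn.
#' @export
make_trn <- function(gt, dropout = 0, spurious_per_regulon = 0L, seed = 1L) {
  stopifnot(inherits(gt, "GroundTruth"))
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  genes <- rownames(gt$true_S)
  with_seed(seed, {
    trn <- lapply(seq_along(gt$regulon_map), function(k) {
      planted <- gt$regulon_map[[k]]
      repeat {
        keep <- planted[stats::runif(length(planted)) >= dropout]
        if (length(keep) > 0) break
      }
      spurious <- character(0)
      if (spurious_per_regulon > 0) {
        pool <- setdiff(genes, planted)
        spurious <- sample(pool, min(spurious_per_regulon, length(pool)))
      }
      sort(c(keep, spurious))
    })
  })
  names(trn) <- paste0("R_", seq_along(gt$regulon_map))
  attr(trn, "annotation_type") <- "regulon"
  trn
}

#' Serialize a ground truth to plain-text files
#'
#' Writes `true_S` and each dataset's `true_A` as TSV matrices plus a JSON
#' sidecar with the scalar parameters and regulon map.
#'
#' @param gt a `GroundTruth`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "true_S.tsv")
  utils::write.table(data.frame(gene_id = rownames(gt$true_S), gt$true_S,
                                check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  for (ds in names(gt$true_A_by_dataset)) {
    p <- file.path(dir, paste0("true_A_", ds, ".tsv"))
    A <- gt$true_A_by_dataset[[ds]]
    utils::write.table(data.frame(component_id = rownames(A), A,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(master_seed = gt$master_seed,
         n_conditions = gt$n_conditions,
         replicates = gt$replicates,
         activity_scale = gt$activity_scale,
         regulon_map = gt$regulon_map,
         noise_sd = as.list(gt$noise_sd),
         provenance = gt$provenance),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
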