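# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Small planted compendium reused by several test files.
tiny_truth <- function(seed = 7, n_genes = 300, n_components = 4,
                       gpc = c(8, 20), n_conditions = 8, replicates = 3) {
  make_ground_truth(n_genes, n_components, gpc,
                    n_conditions = n_conditions, replicates = replicates,
                    activity_scale = 5, seed = seed)
}

# One rendered + centered dataset from a truth.
centered_dataset <- function(gt, id = "D1", noise_sd = 0.05, seed = 11, ...) {
  r <- render_dataset(gt, id, noise_sd = noise_sd, seed = seed, ...)
  list(x = center_to_reference(r$x, r$meta), meta = r$meta,
       gt = r$ground_truth, raw = r$x)
}

# Hand-built expression matrix from a plain matrix.
em <- function(values, dataset_id = "T", centered = FALSE,
               genes = NULL, samples = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, dataset_id, centered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Match decomposition columns to planted components: best |rho| per truth
# column against the estimated S.
match_to_truth <- function(true_S, est_S) {
  cc <- abs(stats::cor(true_S, est_S))
  data.frame(truth = colnames(true_S),
             est = colnames(est_S)[apply(cc, 1, which.max)],
             rho = apply(cc, 1, max))
}
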