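## Consensus independent component analysis.
##
## The decomposition X = S %*% A is estimated by: (1) choosing the number of
## dimensions from the PCA cumulative variance profile; (2) running FastICA
## from many random starts; (3) clustering the pooled candidate components
## with DBSCAN on the distance 1 - |Pearson r| and averaging each cluster
## into a robust centroid; (4) repeating the whole ensemble several times and
## keeping only components that recur in every repetition; (5) recovering
## activities as A = pinv(S) %*% X.

#' Choose the ICA dimensionality from PCA explained variance
#'
#' Returns the smallest number of principal components whose cumulative
#' variance (squared singular values of the centered matrix) reaches
#' `variance_target`.
#'
#' @param x a centered [expression_matrix()] with at least 2 samples.
#' @param variance_target fraction of variance to reconstruct (default 0.99;
#'   0.95 is a pragmatic setting for very large compendia).
#' @return integer dimension.
#' @export
select_dimension <- function(x, variance_target = 0.99) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$centered) stop("dimension selection expects a centered matrix")
  if (ncol(x$values) < 2L) stop("need at least 2 samples")
  d <- svd(x$values, nu = 0, nv = 0)$d
  tot <- sum(d^2)
  if (tot <= 0) stop("zero-variance matrix")
  cum <- cumsum(d^2) / tot
  as.integer(which(cum >= variance_target)[1])
}

## FastICA core ----------------------------------------------------------
## Samples are the observed mixtures and genes the observations, so the
## estimated sources are gene-weighting vectors (the columns of S).

#' One FastICA run (logcosh contrast, symmetric decorrelation)
#'
#' @param x genes x samples centered numeric matrix.
#' @param n_dims number of components (whitening keeps this many PCs).
#' @param tolerance convergence tolerance on the update angle.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the random orthogonal start.
#' @return list with `S` (genes x n_dims, unit-norm, sign-fixed columns) and
#'   `converged` (logical).
#' @keywords internal
fastica_run <- function(x, n_dims, tolerance = 1e-6, max_iter = 500L,
                        seed = 1L) {
  g <- nrow(x)
  # mixtures in rows (samples), observations in columns (genes); each
  # mixture is centered over genes before whitening, as FastICA requires
  xt <- t(x)
  xt <- xt - rowMeans(xt)
  cv <- tcrossprod(xt) / g
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_dims)
  ev <- pmax(eg$values[keep], .Machine$double.eps)
  K <- diag(1 / sqrt(ev), n_dims) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xt                        # n_dims x genes, white

  W <- with_seed(seed, {
    w0 <- matrix(stats::rnorm(n_dims * n_dims), n_dims)
    sym_decorrelate(w0)
  })
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    gwz <- tanh(wz)
    gprime <- rowMeans(1 - gwz^2)
    W1 <- gwz %*% t(z) / g - gprime * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tolerance) { converged <- TRUE; break }
  }
  S <- t(W %*% z)                      # genes x n_dims
  S <- fix_column_signs(unit_norm_columns(S))
  colnames(S) <- sprintf("run_c%02d", seq_len(n_dims))
  list(S = S, converged = converged)
}

#' Symmetric decorrelation W <- (W W^T)^{-1/2} W
#' @keywords internal
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% w
}

#' Run a FastICA ensemble from random starts
#'
#' Executes FastICA `n_runs` times with per-run seeds derived from the master
#' seed and pools the resulting candidate gene-weighting vectors. A run that
#' fails to converge is retried once with a fresh derived seed, then skipped
#' with a warning.
#'
#' @param x a centered [expression_matrix()].
#' @param n_dims number of components per run (see [select_dimension()]).
#' @param n_runs number of random restarts (default 100).
#' @param tolerance FastICA convergence tolerance (default 1e-6; 1e-3 is a
#'   pragmatic setting for very large compendia).
#' @param max_iter iteration cap per run.
#' @param seed master seed.
#' @return genes x (n_runs * n_dims) matrix of unit-norm candidate
#'   components (non-convergent runs excluded).
#' @export
run_ica_ensemble <- function(x, n_dims, n_runs = 100L, tolerance = 1e-6,
                             max_iter = 500L, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n_dims > min(dim(x$values))) {
    stop("n_dims exceeds matrix rank bound min(genes, samples)")
  }
  seeds <- derive_seeds(seed, 2L * n_runs)
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    r <- fastica_run(x$values, n_dims, tolerance, max_iter, seeds[i])
    if (!r$converged) {
      r <- fastica_run(x$values, n_dims, tolerance, max_iter,
                       seeds[n_runs + i])
      if (!r$converged) {
        warning("FastICA run ", i, " did not converge after retry; skipped")
        next
      }
    }
    colnames(r$S) <- sprintf("r%03d_c%02d", i, seq_len(n_dims))
    out[[i]] <- r$S
  }
  cand <- do.call(cbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(cand)) stop("no FastICA run converged")
  cand
}

## DBSCAN on precomputed distances ---------------------------------------

#' DBSCAN over a precomputed distance matrix
#'
#' Classic density-based clustering: a point with at least `min_pts`
#' neighbours within `eps` (itself included) is a core point; clusters are
#' the connected regions of core points plus their border points; everything
#' else is noise (cluster 0).
#'
#' @param d symmetric distance matrix.
#' @param eps neighbourhood radius.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer cluster labels (0 = noise).
#' @keywords internal
dbscan_precomputed <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)            # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nbrs[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster candidate components into robust components
#'
#' Pools of ICA candidates are clustered with DBSCAN on the distance
#' `1 - |Pearson r|` between gene-weighting vectors; each cluster is reduced
#' to a centroid: members are sign-aligned to the cluster's first member,
#' averaged, re-normalized to unit L2 norm and sign-fixed. Noise points are
#' discarded.
#'
#' @param candidates genes x m matrix of unit-norm candidate components.
#' @param eps DBSCAN radius on 1 - |r| (default 0.1).
#' @param min_members minimum cluster seed size (default 50, calibrated to
#'   100-restart ensembles; scale with `n_runs`).
#' @return list with `centroids` (genes x n_clusters matrix, possibly 0
#'   columns) and `sizes` (cluster member counts).
#' @export
cluster_components <- function(candidates, eps = 0.1, min_members = 50L) {
  stopifnot(is.matrix(candidates))
  if (ncol(candidates) < min_members) {
    stop("fewer candidates (", ncol(candidates), ") than min_members (",
         min_members, ")")
  }
  d <- 1 - abs(stats::cor(candidates))
  labels <- dbscan_precomputed(d, eps, min_members)
  ks <- setdiff(sort(unique(labels)), 0L)
  if (!length(ks)) {
    warning("DBSCAN found no clusters; returning empty result")
    return(list(centroids = candidates[, 0, drop = FALSE], sizes = integer(0)))
  }
  cent <- vapply(ks, function(k) {
    idx <- which(labels == k)
    ref <- candidates[, idx[1]]
    m <- candidates[, idx, drop = FALSE]
    sgn <- sign(as.numeric(crossprod(ref, m)))
    sgn[sgn == 0] <- 1
    rowMeans(sweep(m, 2L, sgn, "*"))
  }, numeric(nrow(candidates)))
  cent <- fix_column_signs(unit_norm_columns(cent))
  colnames(cent) <- sprintf("rc%02d", seq_along(ks))
  list(centroids = cent, sizes = as.integer(table(labels)[as.character(ks)]))
}

#' Consensus decomposition over repeated ensembles
#'
#' Runs the full ensemble-and-cluster procedure `n_repetitions` times with
#' independent derived seeds. A component is retained only if every
#' repetition produced a centroid with `|r| >= match_threshold` against the
#' reference centroid (from the first repetition); the final gene weighting
#' is the sign-aligned mean of the matched centroids. Activities are then
#' recovered by pseudoinverse projection, `A = pinv(S) %*% X`.
#'
#' @param x a centered [expression_matrix()].
#' @param n_dims components per run; `NULL` selects it via
#'   [select_dimension()] at `variance_target`.
#' @param n_runs FastICA restarts per repetition (default 100).
#' @param n_repetitions number of independent ensemble repetitions
#'   (default 10).
#' @param tolerance FastICA convergence tolerance.
#' @param variance_target PCA variance fraction for dimension selection.
#' @param eps DBSCAN radius (default 0.1).
#' @param min_members DBSCAN minimum cluster seed size (default 50).
#' @param match_threshold minimum |Pearson r| for a centroid in another
#'   repetition to count as the same component (default 0.7).
#' @param max_iter FastICA iteration cap.
#' @param seed master seed; the decomposition is a pure function of
#'   (x, parameters, seed).
#' @return an object of class `Decomposition`: list with `S` (genes x
#'   components), `A` (components x samples), ids and a `provenance` list.
#' @export
run_robust_ica <- function(x, n_dims = NULL, n_runs = 100L,
                           n_repetitions = 10L, tolerance = 1e-6,
                           variance_target = 0.99, eps = 0.1,
                           min_members = 50L, match_threshold = 0.7,
                           max_iter = 500L, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$centered) stop("consensus ICA expects a centered matrix")
  if (is.null(n_dims)) n_dims <- select_dimension(x, variance_target)
  rep_seeds <- derive_seeds(seed, n_repetitions)
  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    cand <- run_ica_ensemble(x, n_dims, n_runs = n_runs,
                             tolerance = tolerance, max_iter = max_iter,
                             seed = rep_seeds[r])
    reps[[r]] <- cluster_components(cand, eps = eps,
                                    min_members = min_members)$centroids
  }
  ref <- reps[[1]]
  if (ncol(ref) == 0L) {
    stop("no robust components in the first repetition; ",
         "consider a larger eps or more runs")
  }
  keep <- logical(ncol(ref))
  cols <- vector("list", ncol(ref))
  for (j in seq_len(ncol(ref))) {
    matched <- list(ref[, j])
    ok <- TRUE
    for (r in seq(2L, length.out = n_repetitions - 1L)) {
      other <- reps[[r]]
      if (ncol(other) == 0L) { ok <- FALSE; break }
      rho <- as.numeric(stats::cor(ref[, j], other))
      i <- which.max(abs(rho))
      if (abs(rho[i]) < match_threshold) { ok <- FALSE; break }
      matched[[length(matched) + 1L]] <- other[, i] * sign(rho[i])
    }
    if (ok) {
      keep[j] <- TRUE
      cols[[j]] <- rowMeans(do.call(cbind, matched))
    }
  }
  if (!any(keep)) {
    stop("no component recurred across all repetitions; ",
         "consider a larger eps or more runs")
  }
  S <- do.call(cbind, cols[keep])
  S <- unit_norm_columns(S)
  # one alternating least-squares refit: FastICA estimates sources on
  # gene-mean-centered mixtures, so the raw centroids sit a rank-one mean
  # offset away from the column space of X; projecting through the activity
  # fit returns S to that space, making X = S A exact on noiseless data
  A0 <- MASS::ginv(S) %*% x$values
  S <- x$values %*% MASS::ginv(A0)
  S <- fix_column_signs(unit_norm_columns(S))
  rownames(S) <- gene_ids(x)
  colnames(S) <- sprintf("IC%02d", seq_len(ncol(S)))
  A <- compute_activities(S, x)
  structure(
    list(S = S, A = A,
         component_ids = colnames(S),
         gene_ids = gene_ids(x),
         sample_ids = sample_ids(x),
         provenance = list(n_dims = n_dims, n_runs = n_runs,
                           n_repetitions = n_repetitions,
                           tolerance = tolerance,
                           variance_target = variance_target,
                           eps = eps, min_members = min_members,
                           match_threshold = match_threshold,
                           master_seed = as.integer(seed),
                           dataset_id = x$dataset_id)),
    class = "Decomposition"
  )
}

#' @export
print.Decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of '%s': %d genes x %d components x %d samples\n",
              x$provenance$dataset_id %||% "?", nrow(x$S), ncol(x$S),
              ncol(x$A)))
  invisible(x)
}

#' Recover activities by pseudoinverse projection
#'
#' `A = pinv(S) %*% X` (Moore-Penrose pseudoinverse via SVD). Exact when X
#' lies in the column space of S; otherwise the least-squares projection.
#'
#' @param s genes x components gene-weighting matrix.
#' @param x a centered [expression_matrix()] (or a plain matrix) with the
#'   same gene order as `s`.
#' @return components x samples activity matrix.
#' @export
compute_activities <- function(s, x) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  if (!is.null(rownames(s)) && !is.null(rownames(v)) &&
      !identical(rownames(s), rownames(v))) {
    stop("gene order of S and X differ")
  }
  sv <- svd(s, nu = 0, nv = 0)$d
  if (min(sv) / max(sv) < 1e-10) {
    warning(sprintf("S is (near-)rank-deficient; condition number %.3g",
                    max(sv) / max(min(sv), .Machine$double.xmin)))
  }
  A <- MASS::ginv(s) %*% v
  rownames(A) <- colnames(s)
  colnames(A) <- colnames(v)
  A
}

#' Write a decomposition to TSV + JSON provenance
#' @param dec a `Decomposition`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_decomposition <- function(dec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- file.path(dir, "S.tsv")
  utils::write.table(data.frame(gene_id = rownames(dec$S), dec$S,
                                check.names = FALSE),
                     ps, sep = "\t", quote = FALSE, row.names = FALSE)
  pa <- file.path(dir, "A.tsv")
  utils::write.table(data.frame(component_id = rownames(dec$A), dec$A,
                                check.names = FALSE),
                     pa, sep = "\t", quote = FALSE, row.names = FALSE)
  pj <- file.path(dir, "decomposition.json")
  jsonlite::write_json(dec$provenance, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(ps, pa, pj))
}

#' Read a decomposition written by [write_decomposition()]
#' @param dir directory containing S.tsv, A.tsv, decomposition.json.
#' @return a `Decomposition`.
#' @export
read_decomposition <- function(dir) {
  S <- as.matrix(utils::read.delim(file.path(dir, "S.tsv"), row.names = 1L,
                                   check.names = FALSE))
  A <- as.matrix(utils::read.delim(file.path(dir, "A.tsv"), row.names = 1L,
                                   check.names = FALSE))
  prov <- jsonlite::read_json(file.path(dir, "decomposition.json"),
                              simplifyVector = TRUE)
  structure(list(S = S, A = A, component_ids = colnames(S),
                 gene_ids = rownames(S), sample_ids = colnames(A),
                 provenance = prov),
            class = "Decomposition")
}
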