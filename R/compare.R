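## Cross-dataset structure comparison: component similarity, reciprocal
## best hits, reproducibility clusters, overlap coefficients and
## linear-combination decomposition of components.

#' Similarity between two gene-weighting vectors
#'
#' Absolute Pearson correlation over the shared genes; the complementary
#' distance `1 - |r|` is the metric used throughout component clustering and
#' matching.
#'
#' @param u,v named numeric vectors of gene weightings.
#' @param shared_genes gene ids to compare on (>= 3); defaults to the
#'   intersection of the names of `u` and `v`.
#' @return |Pearson r| in `[0, 1]`.
#' @export
component_similarity <- function(u, v,
                                 shared_genes = intersect(names(u), names(v))) {
  if (length(shared_genes) < 3L) stop("need at least 3 shared genes")
  a <- u[shared_genes]
  b <- v[shared_genes]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance weighting vector")
  }
  abs(stats::cor(a, b))
}

#' Build the reciprocal-best-hit graph across decompositions
#'
#' For every pair of datasets, each component's best hit is the partner
#' component with the highest |Pearson r| over their shared genes; an edge
#' is kept only if the best hits are mutual and the similarity is at least
#' `prune_threshold`. Ties are broken toward the smallest component index.
#'
#' @param decompositions named list of `Decomposition` objects (>= 2); names
#'   are the dataset ids.
#' @param prune_threshold minimum similarity for an edge (default 0.3).
#' @return an object of class `RBHGraph`: list with `nodes` (data.frame
#'   dataset_id, component_id), `edges` (data.frame dataset_a, comp_a,
#'   dataset_b, comp_b, similarity) and `prune_threshold`.
#' @export
build_rbh_graph <- function(decompositions, prune_threshold = 0.3) {
  stopifnot(is.list(decompositions), length(decompositions) >= 2L)
  if (is.null(names(decompositions)) || anyDuplicated(names(decompositions))) {
    stop("decompositions must be a uniquely named list")
  }
  ds <- names(decompositions)
  nodes <- do.call(rbind, lapply(ds, function(d) {
    data.frame(dataset_id = d,
               component_id = colnames(decompositions[[d]]$S))
  }))
  edges <- list()
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i >= j) next
    Si <- decompositions[[i]]$S
    Sj <- decompositions[[j]]$S
    shared <- intersect(rownames(Si), rownames(Sj))
    if (length(shared) < 3L) {
      warning("datasets '", ds[i], "' and '", ds[j],
              "' share fewer than 3 genes; pair skipped")
      next
    }
    sim <- abs(stats::cor(Si[shared, , drop = FALSE],
                          Sj[shared, , drop = FALSE]))
    # best hit per row/column; which.max takes the first (smallest index) tie
    best_j <- apply(sim, 1L, which.max)
    best_i <- apply(sim, 2L, which.max)
    for (a in seq_len(nrow(sim))) {
      b <- best_j[a]
      if (best_i[b] == a && sim[a, b] >= prune_threshold) {
        edges[[length(edges) + 1L]] <- data.frame(
          dataset_a = ds[i], comp_a = rownames(sim)[a],
          dataset_b = ds[j], comp_b = colnames(sim)[b],
          similarity = sim[a, b])
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(dataset_a = character(0), comp_a = character(0),
               dataset_b = character(0), comp_b = character(0),
               similarity = numeric(0))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 prune_threshold = prune_threshold),
            class = "RBHGraph")
}

#' @export
print.RBHGraph <- function(x, ...) {
  cat(sprintf("RBHGraph: %d nodes, %d edges (pruned below %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$prune_threshold))
  invisible(x)
}

#' Connected clusters of the RBH graph, with reproducibility tiers
#'
#' Clusters are the connected components of the pruned graph. A cluster is
#' `complex` if any dataset contributes two or more nodes; otherwise
#' `highly-reproducible` if it holds one node from every dataset;
#' `moderately-reproducible` if it spans more than half but not all of the
#' datasets; `dataset-specific` otherwise (including unlinked single nodes).
#'
#' @param g an `RBHGraph`.
#' @param n_datasets total number of datasets compared (defaults to the
#'   number of distinct dataset ids among the nodes).
#' @return data.frame with cluster id, member node keys, datasets spanned
#'   and tier.
#' @export
find_clusters <- function(g, n_datasets = length(unique(g$nodes$dataset_id))) {
  stopifnot(inherits(g, "RBHGraph"))
  key <- function(d, c) paste(d, c, sep = "/")
  nodes <- key(g$nodes$dataset_id, g$nodes$component_id)
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      a <- find(which(nodes == key(g$edges$dataset_a[e], g$edges$comp_a[e])))
      b <- find(which(nodes == key(g$edges$dataset_b[e], g$edges$comp_b[e])))
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_along(nodes), root), function(idx) {
    dsets <- g$nodes$dataset_id[idx]
    n_span <- length(unique(dsets))
    tier <- if (any(table(dsets) >= 2L)) "complex"
    else if (n_span == n_datasets) "highly-reproducible"
    else if (n_span > floor(n_datasets / 2) && n_span < n_datasets)
      "moderately-reproducible"
    else "dataset-specific"
    data.frame(members = paste(nodes[idx], collapse = ","),
               n_nodes = length(idx), n_datasets = n_span, tier = tier)
  }))
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("cluster_id", "members", "n_nodes", "n_datasets", "tier")]
}

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|a intersect b| / min(|a|, |b|)` between two nonempty gene sets.
#'
#' @param a,b nonempty character vectors.
#' @return value in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty gene set")
  a <- unique(a)
  b <- unique(b)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Explain one component as a linear combination of others
#'
#' Selects the `n_select` candidate components with the highest absolute
#' Pearson correlation to the target gene-weighting vector and fits an
#' ordinary least-squares regression of the target on them (with intercept).
#' Used to show that an apparently merged component of one dataset is a
#' linear mixture of components resolved in another.
#'
#' @param target named numeric gene-weighting vector.
#' @param candidates genes x components weighting matrix sharing the
#'   target's gene space.
#' @param n_select number of candidate components to regress on
#'   (default 10).
#' @param intercept include an intercept (default `TRUE`).
#' @return list with `coefficients` (named), `intercept`, `r_squared` and
#'   `selected` (the candidate ids used, by decreasing |r|).
#' @export
fit_linear_combination <- function(target, candidates, n_select = 10L,
                                   intercept = TRUE) {
  shared <- intersect(names(target), rownames(candidates))
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  y <- target[shared]
  X <- candidates[shared, , drop = FALSE]
  n_select <- min(n_select, ncol(X))
  rho <- abs(as.numeric(stats::cor(y, X)))
  sel <- order(-rho)[seq_len(n_select)]
  Xs <- X[, sel, drop = FALSE]
  qrx <- qr(if (intercept) cbind(`(Intercept)` = 1, Xs) else Xs)
  if (qrx$rank < ncol(Xs) + intercept) {
    warning(sprintf("selected candidates are collinear (rank %d of %d); least-norm fit used",
                    qrx$rank, ncol(Xs) + intercept))
    Xm <- if (intercept) cbind(`(Intercept)` = 1, Xs) else Xs
    beta <- as.numeric(MASS::ginv(Xm) %*% y)
    names(beta) <- colnames(Xm)
  } else {
    beta <- qr.coef(qrx, y)
  }
  Xm <- if (intercept) cbind(`(Intercept)` = 1, Xs) else Xs
  fitted <- as.numeric(Xm %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  list(coefficients = beta[colnames(Xs)],
       intercept = if (intercept) unname(beta["(Intercept)"]) else 0,
       r_squared = 1 - rss / tss,
       selected = colnames(Xs))
}

#' Write RBH edges as TSV and DOT
#'
#' @param g an `RBHGraph`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_rbh_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pe <- file.path(dir, "rbh_edges.tsv")
  utils::write.table(g$edges, pe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pd <- file.path(dir, "rbh_graph.dot")
  lines <- c("graph rbh {")
  if (nrow(g$edges)) {
    lines <- c(lines, sprintf('  "%s/%s" -- "%s/%s" [weight=%.3f];',
                              g$edges$dataset_a, g$edges$comp_a,
                              g$edges$dataset_b, g$edges$comp_b,
                              g$edges$similarity))
  }
  lines <- c(lines, "}")
  writeLines(lines, pd)
  invisible(c(pe, pd))
}
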