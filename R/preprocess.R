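## QC filtering, gene harmonization, reference-condition centering and
## concatenation of expression datasets.

#' Drop expression profiles with too many missing values
#'
#' Profiles (samples) with strictly more than `max_missing` missing entries
#' are discarded; survivor order is preserved. This is the standard QC rule
#' for public microarray compendia exported with empty cells.
#'
#' @param x an uncentered [expression_matrix()] (may contain `NA`).
#' @param max_missing maximum tolerated missing count per profile
#'   (default 300).
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_profiles_missing <- function(x, max_missing = 300L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$centered) stop("profile filtering applies to uncentered data")
  n_missing <- colSums(is.na(x$values))
  keep <- n_missing <= max_missing
  if (!any(keep)) stop("all profiles removed by missing-value filter")
  expression_matrix(x$values[, keep, drop = FALSE], x$dataset_id,
                    centered = FALSE)
}

#' Drop genes with any missing value
#'
#' After profile filtering, genes with one or more missing entries across the
#' remaining samples are removed so the centered matrix is dense.
#'
#' @param x an [expression_matrix()].
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_genes_missing <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- rowSums(is.na(x$values)) == 0L
  if (!any(keep)) stop("all genes removed by missing-value filter")
  expression_matrix(x$values[keep, , drop = FALSE], x$dataset_id,
                    centered = x$centered)
}

#' Drop replicate profiles that disagree with all their mates
#'
#' Within each replicate group of size >= 2, a profile is discarded when its
#' *maximum* Pearson correlation with any other member of the group falls
#' below `min_r`. This is the most permissive reading of a replicate
#' correlation QC rule: a profile is kept as soon as it agrees with at least
#' one mate. Singleton groups are untouched.
#'
#' @param x an [expression_matrix()].
#' @param meta the paired [sample_table()].
#' @param min_r Pearson threshold (default 0.2).
#' @return list with the filtered `x` and `meta`.
#' @export
filter_replicate_correlation <- function(x, meta, min_r = 0.2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  check_paired(x, meta)
  meta <- meta[match(sample_ids(x), meta$sample_id), , drop = FALSE]
  drop <- character(0)
  for (grp in unique(meta$replicate_group)) {
    members <- meta$sample_id[meta$replicate_group == grp]
    if (length(members) < 2L) next
    cc <- stats::cor(x$values[, members, drop = FALSE],
                     use = "pairwise.complete.obs")
    diag(cc) <- NA_real_
    best <- apply(cc, 2L, max, na.rm = TRUE)
    bad <- members[best < min_r]
    if (length(bad) == length(members)) {
      warning("replicate group '", grp, "' removed entirely (no pair with r >= ",
              min_r, ")")
    }
    drop <- c(drop, bad)
  }
  keep <- setdiff(sample_ids(x), drop)
  if (!length(keep)) stop("all profiles removed by replicate-correlation filter")
  list(
    x = expression_matrix(x$values[, keep, drop = FALSE], x$dataset_id,
                          centered = x$centered),
    meta = meta[meta$sample_id %in% keep, , drop = FALSE]
  )
}

#' Restrict datasets to their common genes
#'
#' Cross-platform integration keeps only genes measured in every dataset.
#' All outputs share the same (lexicographically sorted) gene order.
#'
#' @param xs list of at least two [expression_matrix()] objects.
#' @return list of restricted matrices, same length and order as `xs`.
#' @export
intersect_genes <- function(xs) {
  stopifnot(is.list(xs), length(xs) >= 2L)
  common <- Reduce(intersect, lapply(xs, gene_ids))
  if (!length(common)) stop("empty gene intersection across datasets")
  common <- sort(common)
  lapply(xs, function(x) {
    expression_matrix(x$values[common, , drop = FALSE], x$dataset_id,
                      centered = x$centered)
  })
}

#' Center a dataset on its reference condition
#'
#' Subtracts from every sample each gene's mean over the dataset's reference
#' samples, so expression becomes log fold change relative to the
#' dataset-specific baseline. This is the only normalization applied before
#' datasets are concatenated.
#'
#' @param x an uncentered, dense [expression_matrix()].
#' @param meta the paired [sample_table()]; rows with `is_reference = TRUE`
#'   and matching `dataset_id` define the baseline.
#' @return the centered `ExpressionMatrix`.
#' @export
center_to_reference <- function(x, meta) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  check_paired(x, meta)
  if (anyNA(x$values)) {
    stop("matrix contains missing values; run the missing-value filters first")
  }
  ref <- meta$sample_id[meta$is_reference & meta$dataset_id == x$dataset_id]
  ref <- intersect(ref, sample_ids(x))
  if (!length(ref)) {
    stop("no reference samples for dataset '", x$dataset_id, "'")
  }
  baseline <- rowMeans(x$values[, ref, drop = FALSE])
  expression_matrix(x$values - baseline, x$dataset_id, centered = TRUE)
}

#' Concatenate centered datasets into a compendium
#'
#' Column-binds the centered matrices without rescaling or batch correction.
#' Sample ids are prefixed with their dataset id to guarantee uniqueness.
#'
#' @param xs list of centered [expression_matrix()] objects with identical
#'   gene order (run [intersect_genes()] first).
#' @param metas list of the paired [sample_table()]s.
#' @return list with the combined `x` (dataset_id `"combined"`) and `meta`.
#' @export
concatenate_datasets <- function(xs, metas) {
  stopifnot(is.list(xs), length(xs) >= 1L, length(xs) == length(metas))
  if (!all(vapply(xs, function(x) x$centered, logical(1)))) {
    stop("all datasets must be centered before concatenation")
  }
  g0 <- gene_ids(xs[[1]])
  for (x in xs[-1]) {
    if (!identical(gene_ids(x), g0)) {
      stop("gene order mismatch; run intersect_genes() first")
    }
  }
  mats <- vector("list", length(xs))
  metas2 <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    m <- metas[[i]]
    check_paired(x, m)
    m <- m[match(sample_ids(x), m$sample_id), , drop = FALSE]
    new_ids <- paste(x$dataset_id, sample_ids(x), sep = ":")
    v <- x$values
    colnames(v) <- new_ids
    m$sample_id <- new_ids
    mats[[i]] <- v
    metas2[[i]] <- m
  }
  values <- do.call(cbind, mats)
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids after dataset prefixing")
  }
  meta <- do.call(rbind, metas2)
  rownames(meta) <- NULL
  class(meta) <- c("SampleTable", "data.frame")
  list(x = expression_matrix(values, dataset_id = "combined", centered = TRUE),
       meta = meta)
}

#' Flag outlier profiles by correlation clustering
#'
#' Optional helper mirroring manual curation of aberrant profiles: profiles
#' are clustered by average linkage on correlation distance (1 - r) and
#' members of singleton branches cut at `h` are flagged. Off by default in
#' the pipeline; it flags candidates, it does not remove them.
#'
#' @param x an [expression_matrix()].
#' @param h cut height on correlation distance (default 0.8).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_profiles <- function(x, h = 0.8) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 3L) return(character(0))
  cc <- stats::cor(x$values, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  grp <- stats::cutree(hc, h = h)
  sizes <- table(grp)
  names(grp)[grp %in% as.integer(names(sizes)[sizes == 1L])]
}
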