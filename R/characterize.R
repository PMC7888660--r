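## iModulon characterization: regulon / gene-set enrichment and category
## assignment (Regulatory, Genomic, Functional, Uncharacterized).

#' One-sided (greater) Fisher exact p for a 2x2 overlap table
#'
#' The upper hypergeometric tail P(X >= overlap) for drawing `imodulon_size`
#' genes from a universe containing `set_size` annotated genes.
#' @keywords internal
fisher_p_greater <- function(overlap, imodulon_size, set_size, universe_size) {
  stats::phyper(overlap - 1L, set_size, universe_size - set_size,
                imodulon_size, lower.tail = FALSE)
}

#' Enrichment of a gene set against a collection of annotations
#'
#' For every annotation set, computes the one-sided Fisher's exact test on
#' the 2x2 table (overlap / iModulon-only / set-only / neither), adjusts
#' p-values with Benjamini-Hochberg over the tested family, and reports
#' precision, recall and F1 of the gene set against each annotation.
#'
#' @param gene_set nonempty character vector (e.g. an iModulon's genes).
#' @param annotations named list of gene sets (regulons, GO terms, ...).
#' @param universe_size size of the gene universe the sets are drawn from;
#'   must be at least the size of every margin.
#' @param fdr significance level applied to the BH-adjusted q-values.
#' @param component_id optional id recorded in the result.
#' @return data.frame (class `EnrichmentResult`) with columns component_id,
#'   set_id, overlap, set_size, imodulon_size, universe_size, p, q,
#'   precision, recall, f1, significant; sorted by q then p.
#' @export
fisher_enrichment <- function(gene_set, annotations, universe_size,
                              fdr = 1e-5, component_id = NA_character_) {
  if (!length(gene_set)) stop("empty gene set")
  if (!length(annotations)) stop("empty annotation collection")
  n_im <- length(unique(gene_set))
  sizes <- lengths(lapply(annotations, unique))
  if (universe_size < n_im || any(universe_size < sizes)) {
    stop("universe smaller than a table margin")
  }
  overlap <- vapply(annotations, function(s) {
    length(intersect(gene_set, s))
  }, integer(1))
  p <- fisher_p_greater(overlap, n_im, sizes, universe_size)
  precision <- overlap / n_im
  recall <- overlap / sizes
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  out <- data.frame(
    component_id = component_id,
    set_id = names(annotations),
    overlap = overlap,
    set_size = as.integer(sizes),
    imodulon_size = n_im,
    universe_size = as.integer(universe_size),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    precision = precision,
    recall = recall,
    f1 = f1,
    row.names = NULL
  )
  out$significant <- out$q < fdr
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Enrich every iModulon of a decomposition against one annotation family
#'
#' Runs [fisher_enrichment()] per iModulon but adjusts the FDR over the
#' whole component x annotation family, so the multiple-testing family is a
#' single coherent screen.
#'
#' @param imodulons named list of `IModulon` objects.
#' @param annotations named list of gene sets.
#' @param universe_size gene universe size.
#' @param fdr significance level.
#' @return one combined `EnrichmentResult` data.frame.
#' @export
enrich_imodulons <- function(imodulons, annotations, universe_size,
                             fdr = 1e-5) {
  parts <- lapply(imodulons, function(im) {
    if (!length(im$gene_set)) return(NULL)
    fisher_enrichment(im$gene_set, annotations, universe_size, fdr = fdr,
                      component_id = im$component_id)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("no nonempty iModulon to enrich")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Assign an iModulon to one of four categories
#'
#' Priority order: *Regulatory* if any regulon enrichment passes
#' `regulon_fdr` (named for the lowest-q regulator); else *Genomic* if a
#' genotype table links the iModulon to a known genetic alteration (overlap
#' coefficient >= `genomic_overlap`; an explicit proxy for manual curation,
#' off unless a table is supplied); else *Functional* if any GO/prophage set
#' passes `go_fdr`; else *Uncharacterized*.
#'
#' @param imodulon an `IModulon`.
#' @param regulon_results `EnrichmentResult` rows for this component against
#'   regulons (may be `NULL`).
#' @param go_results `EnrichmentResult` rows against GO/prophage sets (may be
#'   `NULL`).
#' @param genotype_table optional named list: strain/alteration -> altered
#'   gene set.
#' @param regulon_fdr,go_fdr significance levels (defaults 1e-5 and 0.01).
#' @param genomic_overlap overlap-coefficient threshold for the Genomic rule.
#' @return the `IModulon` with `category` and `name` filled in.
#' @export
categorize <- function(imodulon, regulon_results = NULL, go_results = NULL,
                       genotype_table = NULL, regulon_fdr = 1e-5,
                       go_fdr = 0.01, genomic_overlap = 0.5) {
  pick_best <- function(res, level) {
    if (is.null(res) || !nrow(res)) return(NULL)
    res <- res[res$component_id %in% imodulon$component_id & res$q < level, ,
               drop = FALSE]
    if (!nrow(res)) return(NULL)
    res <- res[order(res$q, res$set_id), , drop = FALSE]
    if (nrow(res) > 1 && res$q[1] == res$q[2]) {
      message("category naming tie for ", imodulon$component_id,
              "; lexicographic winner ", res$set_id[1])
    }
    res$set_id[1]
  }
  reg <- pick_best(regulon_results, regulon_fdr)
  if (!is.null(reg)) {
    imodulon$category <- "Regulatory"
    imodulon$name <- reg
    return(imodulon)
  }
  if (!is.null(genotype_table) && length(imodulon$gene_set)) {
    oc <- vapply(genotype_table, function(alt) {
      overlap_coefficient(imodulon$gene_set, alt)
    }, numeric(1))
    if (any(oc >= genomic_overlap)) {
      imodulon$category <- "Genomic"
      imodulon$name <- names(genotype_table)[which.max(oc)]
      return(imodulon)
    }
  }
  go <- pick_best(go_results, go_fdr)
  if (!is.null(go)) {
    imodulon$category <- "Functional"
    imodulon$name <- go
    return(imodulon)
  }
  imodulon$category <- "Uncharacterized"
  imodulon$name <- imodulon$component_id
  imodulon
}

#' Precision, recall and F1 between an iModulon and a regulon
#'
#' `precision = |intersection| / |iModulon|`,
#' `recall = |intersection| / |regulon|`,
#' `f1 = 2pr / (p + r)` (0 when both are 0).
#'
#' @param imodulon_genes,regulon_genes nonempty character vectors.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
compute_f1 <- function(imodulon_genes, regulon_genes) {
  if (!length(imodulon_genes) || !length(regulon_genes)) {
    stop("empty gene set")
  }
  a <- unique(imodulon_genes)
  b <- unique(regulon_genes)
  ov <- length(intersect(a, b))
  precision <- ov / length(a)
  recall <- ov / length(b)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Write an enrichment table to TSV (all 2x2 margins included)
#' @param res an `EnrichmentResult` data.frame.
#' @param path file path.
#' @export
write_enrichments <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
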