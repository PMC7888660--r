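## iModulon extraction: iterative gene removal against the D'Agostino
## K-squared normality statistic, plus TRN-guided cutoff optimization.

#' D'Agostino K-squared omnibus normality statistic
#'
#' `K2 = Z1(skewness)^2 + Z2(kurtosis)^2` following the
#' D'Agostino-Belanger-D'Agostino (1990) transformations: the skewness
#' z-score uses the Johnson SU approximation, the kurtosis z-score the
#' Anscombe-Glynn approximation. Large values mean heavy tails / asymmetry;
#' an ideal Gaussian sample gives a small K2 (chi-squared with 2 df under
#' normality).
#'
#' @param weights numeric vector, length >= 9, nonzero variance. The
#'   statistic is invariant to affine transforms `a*w + b` (a != 0).
#' @return the K2 statistic (single nonnegative number).
#' @export
dagostino_k2 <- function(weights) {
  w <- as.numeric(weights)
  n <- length(w)
  if (n < 9L) stop("need at least 9 values for the K2 approximations")
  if (stats::var(w) == 0) stop("zero-variance input")
  m <- mean(w)
  m2 <- mean((w - m)^2)
  m3 <- mean((w - m)^3)
  m4 <- mean((w - m)^4)

  # skewness: Johnson SU transform of sqrt(b1)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe-Glynn transform of b2
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  # signed cube root: denom can be negative for strongly platykurtic samples
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  z1^2 + z2^2
}

#' Deterministic gene removal order for an IC
#'
#' Descending absolute weight; ties broken lexicographically by gene id so
#' extraction is reproducible across platforms.
#' @keywords internal
removal_order <- function(weights) {
  ids <- names(weights)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_along(weights))
  order(-abs(weights), ids)
}

#' Extract an iModulon from an IC's gene weightings
#'
#' Iteratively removes the gene of largest absolute weight and recomputes
#' the D'Agostino K2 statistic on the remaining weights; the first time K2
#' drops below `cutoff` (including before any removal), the removed genes
#' form the iModulon. The threshold reported is the smallest absolute weight
#' among member genes (`Inf` for an empty iModulon). Removal stops early —
#' closing the iModulon — if fewer than 9 genes would remain, since K2 is
#' undefined below that.
#'
#' @param weights named numeric vector of gene weightings (one S column).
#' @param cutoff positive K2 stopping cutoff.
#' @param component_id optional id stored on the result.
#' @return an object of class `IModulon`: list with `gene_set`, `threshold`,
#'   `k2_trace` (data.frame of step and K2 after that many removals),
#'   `cutoff`, `component_id`, and placeholders `category`/`name`.
#' @export
extract_imodulon <- function(weights, cutoff, component_id = NA_character_) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(names(weights))) stop("weights must be named by gene id")
  ord <- removal_order(weights)
  w_sorted <- weights[ord]
  n <- length(weights)
  trace_steps <- integer(0)
  trace_k2 <- numeric(0)
  n_removed <- 0L
  repeat {
    remaining <- w_sorted[seq.int(n_removed + 1L, n)]
    if (length(remaining) < 9L) break
    # a constant remainder (e.g. exact zeros of a sparse weighting) carries
    # no more signal; close the iModulon
    if (stats::var(remaining) == 0) break
    k2 <- dagostino_k2(remaining)
    trace_steps <- c(trace_steps, n_removed)
    trace_k2 <- c(trace_k2, k2)
    if (k2 < cutoff) break
    n_removed <- n_removed + 1L
  }
  members <- names(w_sorted)[seq_len(n_removed)]
  structure(
    list(component_id = component_id,
         gene_set = sort(members),
         threshold = if (n_removed) min(abs(w_sorted[seq_len(n_removed)])) else Inf,
         k2_trace = data.frame(step = trace_steps, k2 = trace_k2),
         cutoff = cutoff,
         category = NA_character_,
         name = NA_character_,
         enrichments = NULL),
    class = "IModulon"
  )
}

#' @export
print.IModulon <- function(x, ...) {
  cat(sprintf("IModulon %s: %d genes, |weight| threshold %.4g (K2 cutoff %g)\n",
              x$component_id, length(x$gene_set), x$threshold, x$cutoff))
  invisible(x)
}

#' Extract iModulons for every component of a decomposition
#'
#' @param dec a `Decomposition` (see [run_robust_ica()]).
#' @param cutoff K2 stopping cutoff (see [optimize_cutoff()]).
#' @return named list of [extract_imodulon()] results, one per component.
#' @export
extract_all_imodulons <- function(dec, cutoff) {
  stopifnot(inherits(dec, "Decomposition"))
  out <- lapply(colnames(dec$S), function(k) {
    extract_imodulon(stats::setNames(dec$S[, k], rownames(dec$S)),
                     cutoff, component_id = k)
  })
  stats::setNames(out, colnames(dec$S))
}

#' Link each component to a candidate regulator from its top genes
#'
#' For each component the `top_n` genes by absolute weight are tested for
#' enrichment against every regulon (one-sided Fisher's exact test,
#' Benjamini-Hochberg FDR over all component x regulon tests). Components
#' with at least one enrichment at `fdr` are linked to the regulator with the
#' lowest p-value; the rest get `NA` and are excluded from cutoff
#' optimization.
#'
#' @param s genes x components weighting matrix.
#' @param trn named list of regulons (see [read_trn()] / [make_trn()]).
#' @param top_n genes per component to test (default 20).
#' @param fdr significance level on BH-adjusted q (default 1e-5).
#' @return named character vector, component -> regulator or `NA`.
#' @export
preliminary_enrichment <- function(s, trn, top_n = 20L, fdr = 1e-5) {
  if (!length(trn)) stop("empty TRN")
  universe <- rownames(s)
  if (is.null(universe)) stop("S must have gene rownames")
  trn <- lapply(trn, intersect, universe)
  tests <- expand.grid(component = colnames(s), regulator = names(trn),
                       stringsAsFactors = FALSE)
  top_sets <- lapply(colnames(s), function(k) {
    w <- stats::setNames(s[, k], universe)
    names(w)[removal_order(w)][seq_len(min(top_n, length(w)))]
  })
  names(top_sets) <- colnames(s)
  tests$p <- mapply(function(k, r) {
    fisher_p_greater(length(intersect(top_sets[[k]], trn[[r]])),
                     length(top_sets[[k]]), length(trn[[r]]),
                     length(universe))
  }, tests$component, tests$regulator)
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  out <- stats::setNames(rep(NA_character_, ncol(s)), colnames(s))
  for (k in colnames(s)) {
    sub <- tests[tests$component == k & tests$q < fdr, , drop = FALSE]
    if (nrow(sub)) out[k] <- sub$regulator[which.min(sub$p)]
  }
  out
}

#' Optimize the K2 cutoff against a regulatory network
#'
#' Sweeps the K2 cutoff over a grid (default 200 to 1000 in steps of 50,
#' i.e. 17 values). At each cutoff, iModulons are extracted for every
#' component that has a preliminary regulator link and scored by the
#' F1-score (harmonic mean of precision and recall) against that regulon;
#' the cutoff with the maximum mean F1 wins, ties going to the smallest
#' cutoff.
#'
#' @param s genes x components weighting matrix.
#' @param trn named list of regulons.
#' @param grid_start,grid_stop,grid_step cutoff grid (defaults 200, 1000, 50).
#' @param top_n,fdr passed to [preliminary_enrichment()].
#' @return list with `cutoff` (the optimum), `table` (data.frame cutoff x
#'   mean_f1), and `links` (the preliminary component -> regulator map).
#' @export
optimize_cutoff <- function(s, trn, grid_start = 200, grid_stop = 1000,
                            grid_step = 50, top_n = 20L, fdr = 1e-5) {
  links <- preliminary_enrichment(s, trn, top_n = top_n, fdr = fdr)
  linked <- names(links)[!is.na(links)]
  if (!length(linked)) {
    stop("no component has a significant preliminary regulator; ",
         "use the default cutoff (550) instead")
  }
  grid <- seq(grid_start, grid_stop, by = grid_step)
  mean_f1 <- vapply(grid, function(ct) {
    f1s <- vapply(linked, function(k) {
      im <- extract_imodulon(stats::setNames(s[, k], rownames(s)), ct,
                             component_id = k)
      reg <- trn[[links[k]]]
      if (!length(im$gene_set)) return(0)
      compute_f1(im$gene_set, reg)["f1"]
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  best <- grid[which.max(mean_f1)]    # which.max returns the first (smallest) tie
  list(cutoff = best,
       table = data.frame(cutoff = grid, mean_f1 = mean_f1),
       links = links)
}

#' Export iModulon gene sets
#'
#' Writes the gene sets as GMT, a long-format membership TSV
#' (component, gene, weight) and the K2 traces as TSV.
#'
#' @param imodulons named list of `IModulon` objects.
#' @param s the weighting matrix the iModulons came from.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_imodulons <- function(imodulons, s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(imodulons, `[[`, "gene_set")
  names(sets) <- vapply(imodulons, `[[`, character(1), "component_id")
  pg <- file.path(dir, "imodulons.gmt")
  write_gmt(sets[lengths(sets) > 0], pg)
  long <- do.call(rbind, lapply(imodulons, function(im) {
    if (!length(im$gene_set)) return(NULL)
    data.frame(component = im$component_id, gene = im$gene_set,
               weight = s[im$gene_set, im$component_id])
  }))
  pm <- file.path(dir, "imodulon_members.tsv")
  utils::write.table(long, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- do.call(rbind, lapply(imodulons, function(im) {
    if (!nrow(im$k2_trace)) return(NULL)
    cbind(component = im$component_id, im$k2_trace)
  }))
  pt <- file.path(dir, "k2_traces.tsv")
  utils::write.table(tr, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pg, pm, pt))
}
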