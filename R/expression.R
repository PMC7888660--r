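## Core data containers: expression matrices and sample metadata.

#' Construct an expression matrix
#'
#' The central container of the package: a genes x samples matrix of
#' log-scale expression values (log2 intensities, log-TPM, or centered
#' log-ratios) together with its dataset identity and centering state.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param dataset_id single string naming the dataset the samples belong to.
#'   Concatenated compendia use the ids recorded in the sample table instead.
#' @param centered logical; `TRUE` once the dataset has been centered on its
#'   reference condition (see [center_to_reference()]).
#' @return an object of class `ExpressionMatrix`.
#' @seealso [read_expression_tsv()], [center_to_reference()]
#' @export
expression_matrix <- function(values, dataset_id, centered = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (isTRUE(centered) && anyNA(values)) {
    stop("a centered matrix may not contain missing values")
  }
  structure(
    list(values = values,
         dataset_id = as.character(dataset_id),
         centered = isTRUE(centered)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples (%s)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              if (x$centered) "centered" else "uncentered"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Construct a sample metadata table
#'
#' @param sample_id,dataset_id,condition_id,replicate_group character vectors
#'   of equal length describing each expression profile.
#' @param is_reference logical vector flagging the samples of each dataset's
#'   reference condition (the baseline subtracted during centering).
#' @return a `data.frame` with class `SampleTable`.
#' @export
sample_table <- function(sample_id, dataset_id, condition_id,
                         replicate_group, is_reference) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    dataset_id = as.character(dataset_id),
    condition_id = as.character(condition_id),
    replicate_group = as.character(replicate_group),
    is_reference = as.logical(is_reference),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  for (ds in unique(df$dataset_id)) {
    if (!any(df$is_reference[df$dataset_id == ds])) {
      stop(sprintf("dataset '%s' has no reference sample", ds))
    }
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Check that a sample table describes the samples of an expression matrix
#' @keywords internal
check_paired <- function(x, meta) {
  missing <- setdiff(sample_ids(x), meta$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

## TSV round trips -------------------------------------------------------
## Dialect: genes x samples with a header row of sample ids; empty cells are
## missing values (the usual export convention of public compendia).

#' Read an expression matrix from TSV
#'
#' Expects genes in rows, a header row of sample ids, and the gene id in the
#' first column. Empty cells parse to `NA`.
#'
#' @param path file path.
#' @param dataset_id dataset identifier to attach.
#' @param centered logical; whether the stored values are already centered.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, dataset_id, centered = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          na.strings = c("NA", ""))
  expression_matrix(as.matrix(df), dataset_id = dataset_id,
                    centered = centered)
}

#' Write an expression matrix to TSV
#' @param x an [expression_matrix()].
#' @param path file path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample table from TSV
#' @param path file path with columns sample_id, dataset_id, condition_id,
#'   replicate_group, is_reference.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("sample_id", "dataset_id", "condition_id", "replicate_group",
            "is_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  sample_table(df$sample_id, df$dataset_id, df$condition_id,
               df$replicate_group, as.logical(df$is_reference))
}

#' Write a sample table to TSV
#' @param meta a [sample_table()].
#' @param path file path.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Gene-set annotations ---------------------------------------------------

#' Read a regulator-to-gene table (TRN) from TSV
#'
#' A transcriptional regulatory network stored as a two-column table
#' (regulator, gene) is turned into a named list of regulons.
#'
#' @param path TSV with columns `regulator` and `gene` (header required).
#' @return named list of character vectors (one regulon per regulator), with
#'   attribute `annotation_type = "regulon"`.
#' @export
read_trn <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("regulator", "gene") %in% names(df))) {
    stop("TRN file must have 'regulator' and 'gene' columns")
  }
  sets <- split(df$gene, df$regulator)
  sets <- lapply(sets, unique)
  attr(sets, "annotation_type") <- "regulon"
  sets
}

#' Write a regulon list as a two-column TSV
#' @param trn named list of gene vectors.
#' @param path file path.
#' @export
write_trn <- function(trn, path) {
  df <- data.frame(
    regulator = rep(names(trn), lengths(trn)),
    gene = unlist(trn, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description optional description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
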