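## Activity inference for expression contrasts and activity reproducibility
## summaries.

#' Project an expression contrast onto component activities
#'
#' Given two mean expression profiles centered to the same reference, the
#' gene-wise difference `delta_X = x_b - x_a` is projected onto a fixed
#' gene-weighting matrix: `delta_A = pinv(S) %*% delta_X`. Per-component and
#' joint explained variance of the contrast are reported alongside.
#'
#' @param s genes x components weighting matrix.
#' @param x_a,x_b named numeric mean profiles on the same gene order as `s`.
#' @return an object of class `ContrastResult`: list with `delta_X`,
#'   `delta_A`, `explained_variance` (per component), `joint_ev` and
#'   `residual_fraction` (`1 - joint_ev`).
#' @export
project_contrast <- function(s, x_a, x_b) {
  if (!identical(names(x_a), rownames(s)) ||
      !identical(names(x_b), rownames(s))) {
    stop("gene order of profiles and S differ")
  }
  delta_X <- x_b - x_a
  delta_A <- as.numeric(MASS::ginv(s) %*% delta_X)
  names(delta_A) <- colnames(s)
  ss_tot <- sum(delta_X^2)
  ev <- if (ss_tot > 0) {
    vapply(seq_len(ncol(s)), function(k) {
      explained_variance(delta_X, s, delta_A, k)
    }, numeric(1))
  } else {
    rep(NA_real_, ncol(s))
  }
  names(ev) <- colnames(s)
  joint <- if (ss_tot > 0) {
    1 - sum((delta_X - as.numeric(s %*% delta_A))^2) / ss_tot
  } else NA_real_
  structure(
    list(delta_X = delta_X, delta_A = delta_A,
         explained_variance = ev, joint_ev = joint,
         residual_fraction = 1 - joint),
    class = "ContrastResult"
  )
}

#' @export
print.ContrastResult <- function(x, ...) {
  cat(sprintf("ContrastResult: %d genes, %d components, joint EV %.3f\n",
              length(x$delta_X), length(x$delta_A), x$joint_ev))
  invisible(x)
}

#' Explained variance of a contrast by one component
#'
#' `EV_k = (sum(dX^2) - sum((dX - S_k * dA_k)^2)) / sum(dX^2)`: the fraction
#' of the squared expression change captured when only component `k`'s
#' activity change is modeled. Negative values are reported raw — they mean
#' the component misfits the contrast.
#'
#' @param delta_X gene-wise expression difference (nonzero).
#' @param s genes x components weighting matrix.
#' @param delta_A activity-change vector (see [project_contrast()]).
#' @param k component index or id.
#' @return a real number (at most 1).
#' @export
explained_variance <- function(delta_X, s, delta_A, k) {
  ss_tot <- sum(delta_X^2)
  if (ss_tot == 0) stop("zero contrast")
  resid_k <- delta_X - s[, k] * delta_A[k]
  (ss_tot - sum(resid_k^2)) / ss_tot
}

#' Replicate reproducibility of activities
#'
#' For each component: within every replicate group of size >= 2, the
#' standard deviation of the activity values; normalized by the component's
#' activity range across all samples; averaged over groups. Components that
#' track biology have near-identical activities within replicate groups and
#' score low; components that absorb noise score high.
#'
#' @param a components x samples activity matrix.
#' @param meta the paired [sample_table()].
#' @param normalize `"range"` (default) divides within-group SDs by the
#'   component's activity range; `"sd"` divides by its overall SD.
#' @return data.frame with component_id, rsd (the summary), n_groups.
#' @export
replicate_rsd <- function(a, meta, normalize = c("range", "sd")) {
  normalize <- match.arg(normalize)
  meta <- meta[match(colnames(a), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("activity columns missing from metadata")
  # replicate groups are meaningful within a dataset only
  groups <- split(seq_len(ncol(a)),
                  paste(meta$dataset_id, meta$replicate_group, sep = ":"))
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) stop("no replicate group of size >= 2")
  res <- vapply(seq_len(nrow(a)), function(k) {
    scale_k <- if (normalize == "range") diff(range(a[k, ])) else
      stats::sd(a[k, ])
    if (scale_k == 0) return(NA_real_)
    mean(vapply(groups, function(idx) stats::sd(a[k, idx]), numeric(1))) /
      scale_k
  }, numeric(1))
  data.frame(component_id = rownames(a) %||% as.character(seq_len(nrow(a))),
             rsd = res, n_groups = length(groups))
}

#' Write a contrast report to TSV
#' @param cr a `ContrastResult`.
#' @param path file path.
#' @export
write_contrast <- function(cr, path) {
  utils::write.table(
    data.frame(component_id = names(cr$delta_A),
               delta_A = cr$delta_A,
               explained_variance = cr$explained_variance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
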