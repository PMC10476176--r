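# Count filtering and TMM-RPKM log normalization.  Filters operate on the
# counts scale and treat masked (absent-ortholog) cells as excluded from both
# numerator and denominator -- an absent ortholog must not mimic low
# expression.

#' Remove abnormally low-expressed genes
#'
#' Drops genes whose count is below `min_value` in `min_samples` or more
#' observed samples.  Masked cells count as neither pass nor fail.
#'
#' @param x `expr_matrix` of counts.
#' @param min_value Count threshold (default 10).
#' @param min_samples Number of low samples that triggers removal (4).
#' @return Filtered `expr_matrix`; removed gene ids in attribute
#'   `"removed"`.
#' @export
filter_low_expression <- function(x, min_value = 10, min_samples = 4) {
  stopifnot(inherits(x, "expr_matrix"), x$scale_tag == "counts")
  if (nrow(x$values) == 0) stop("empty matrix")
  n_low <- rowSums(x$values < min_value, na.rm = TRUE)
  drop <- n_low >= min_samples
  subset_genes(x, !drop, removed = rownames(x$values)[drop])
}

#' Remove dominant genes
#'
#' Drops genes whose summed counts account for `share` or more of the grand
#' total -- single extremely expressed genes distort composition factors.
#'
#' @param x `expr_matrix` of counts.
#' @param share Fraction of the grand total (default 0.05).
#' @return Filtered `expr_matrix` with attribute `"removed"`.
#' @export
filter_dominant_gene <- function(x, share = 0.05) {
  stopifnot(inherits(x, "expr_matrix"), x$scale_tag == "counts")
  tot <- sum(x$values, na.rm = TRUE)
  if (tot == 0) stop("grand total is zero")
  gene_tot <- rowSums(x$values, na.rm = TRUE)
  drop <- gene_tot / tot >= share
  subset_genes(x, !drop, removed = rownames(x$values)[drop])
}

#' Remove genes present in too few species
#'
#' @param x `expr_matrix` with a presence mask.
#' @param min_species Minimum species with a called ortholog (68 at the
#'   full 103-species scale; set lower for desk-scale trees).
#' @return Filtered `expr_matrix` with attribute `"removed"`.
#' @export
filter_min_species <- function(x, min_species = 68) {
  stopifnot(inherits(x, "expr_matrix"))
  n_sp <- rowSums(x$presence)
  drop <- n_sp < min_species
  subset_genes(x, !drop, removed = rownames(x$values)[drop])
}

subset_genes <- function(x, keep, removed = character(0)) {
  out <- expression_matrix(x$values[keep, , drop = FALSE], x$samples,
                           scale_tag = x$scale_tag,
                           presence = x$presence[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Library-composition factors computed exactly in the standard way: the
#' reference sample is the one whose 75th percentile of count/library is
#' closest to the mean of those percentiles; per-sample log2 ratios (M) are
#' trimmed by 30% on M and 5% on absolute intensity (A), and averaged with
#' inverse-asymptotic-variance precision weights.  Factors are normalized
#' to multiply to 1.
#'
#' @param x `expr_matrix` of counts.
#' @param reference `"auto"` or a sample id.
#' @param logratio_trim,sum_trim Trim fractions (0.30 / 0.05).
#' @return Named numeric factor vector (product 1).
#' @export
tmm_factors <- function(x, reference = "auto",
                        logratio_trim = 0.30, sum_trim = 0.05) {
  stopifnot(inherits(x, "expr_matrix"), x$scale_tag == "counts")
  counts <- x$values
  if (ncol(counts) < 2) stop("need >= 2 samples")
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    cj <- counts[, j]
    stats::quantile(cj[!is.na(cj)] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- if (identical(reference, "auto"))
    which.min(abs(f75 - mean(f75))) else match(reference, colnames(counts))
  if (is.na(ref)) stop("unknown reference sample: ", reference)
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample vs reference; the two-sided trim follows the standard
# rank-window construction of the method.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  ok <- !is.na(obs) & !is.na(ref) & obs > 0 & ref > 0
  obs <- obs[ok]; ref <- ref[ok]
  if (length(obs) == 0) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  2^(sum(w[keep]^-1 * M[keep]) / sum(w[keep]^-1))
}

#' Log2 TMM-RPKM normalization
#'
#' `value = log2(count * 1e9 / (effective_library * length) + 1)` with
#' `effective_library = raw library size * TMM factor`.  The log transform
#' damps the influence of very high expression and reduces variation among
#' replicates; on fragment counts RPKM is equivalent to FPKM.
#'
#' @param x `expr_matrix` of counts.
#' @param gene_lengths Named lengths in bp (one per gene; the study uses
#'   human transcript lengths for all species).
#' @param factors Factors from [tmm_factors()]; computed if `NULL`.
#' @return `expr_matrix` with `scale_tag = "log2_tmm_rpkm"`.
#' @export
log2_tmm_rpkm <- function(x, gene_lengths, factors = NULL) {
  stopifnot(inherits(x, "expr_matrix"), x$scale_tag == "counts")
  len <- gene_lengths[rownames(x$values)]
  if (anyNA(len)) stop("missing length for gene(s): ",
                       paste(rownames(x$values)[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (is.null(factors)) factors <- tmm_factors(x)
  lib <- colSums(x$values, na.rm = TRUE) * factors[colnames(x$values)]
  rpkm <- sweep(sweep(x$values, 2, lib, "/"), 1, len, "/") * 1e9
  expression_matrix(log2(rpkm + 1), x$samples, scale_tag = "log2_tmm_rpkm",
                    presence = x$presence)
}

#' PCA on the top-variance genes
#'
#' Genes are ranked by variance of the normalized values; the top `n_top`
#' (all, if fewer) are mean-centered and decomposed.  Masked cells are
#' completed with the per-gene mean for the decomposition only.
#'
#' @param mat Gene x sample (or gene x species) numeric matrix, log scale.
#' @param n_top Number of top-variance genes (default 5000).
#' @return `list(scores, sdev, explained, genes)`; `explained` fractions
#'   are non-increasing.
#' @export
pca_top_variance <- function(mat, n_top = 5000) {
  if (ncol(mat) < 2) stop("need >= 2 columns")
  v <- apply(mat, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(mat)))]
  m <- mat[top, , drop = FALSE]
  if (anyNA(m)) {
    rm <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm[idx[, 1]]
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, sdev = pc$sdev, explained = expl,
       genes = rownames(mat)[top])
}
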