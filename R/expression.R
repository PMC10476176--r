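#' Construct an expression matrix with an ortholog presence mask
#'
#' The container used throughout the pipeline: a numeric gene x sample
#' matrix plus a per-sample metadata table and a gene x species presence
#' mask.  A gene absent in a species (no ortholog called) is a *masked*
#' state, stored as `NA` in every sample of that species -- it is never a
#' zero count, and filters and regressions exclude it from their
#' denominators.
#'
#' @param values Numeric matrix, rows = genes, columns = samples; `NA`
#'   marks masked cells.
#' @param samples A sample table (data.frame) with columns `sample_id`,
#'   `species`, `tissue`, `replicate`, `batch`; row order free.
#' @param scale_tag `"counts"` or `"log2_tmm_rpkm"`.
#' @param presence Optional gene x species logical matrix; derived from
#'   `values` (a gene is present in a species when at least one of its
#'   samples is observed) when omitted.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              scale_tag = c("counts", "log2_tmm_rpkm"),
                              presence = NULL) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  samples <- validate_sample_table(samples)
  if (!setequal(samples$sample_id, colnames(values)))
    stop("sample ids in metadata do not match matrix columns; missing: ",
         paste(setdiff(colnames(values), samples$sample_id), collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (scale_tag == "counts" && any(values < 0, na.rm = TRUE))
    stop("negative counts")
  if (is.null(presence)) {
    presence <- derive_presence(values, samples$species)
  } else {
    presence <- as.matrix(presence)
  }
  structure(list(values = values, samples = samples,
                 presence = presence, scale_tag = scale_tag),
            class = "expr_matrix")
}

validate_sample_table <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "species", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in metadata")
  samples$species <- normalize_species(samples$species)
  if (is.null(samples$replicate)) samples$replicate <- 1L
  if (is.null(samples$batch)) samples$batch <- "batch1"
  samples
}

derive_presence <- function(values, species) {
  sp <- unique(species)
  pres <- vapply(sp, function(s) {
    cols <- which(species == s)
    rowSums(!is.na(values[, cols, drop = FALSE])) > 0
  }, logical(nrow(values)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = nrow(values))
  dimnames(pres) <- list(rownames(values), sp)
  pres
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples, %d species; %.1f%% masked\n",
              x$scale_tag, nrow(x$values), ncol(x$values),
              length(unique(x$samples$species)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix TSV has a header row of sample ids and gene ids in the first
#' column; cells are numeric or `NA` (masked).  The metadata TSV is keyed by
#' `sample_id`.  Cross-validation failures (samples without metadata,
#' duplicate ids, non-numeric cells) are errors, not warnings.
#'
#' @param path Matrix TSV path.
#' @param metadata_path Metadata TSV path.
#' @param scale_tag Scale of the stored values.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, metadata_path,
                            scale_tag = c("counts", "log2_tmm_rpkm")) {
  scale_tag <- match.arg(scale_tag)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs gene ids plus >= 1 sample")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) & !is.na(vals) & vals != "NA")
    if (length(bad)) stop("non-numeric cells in ", path)
    vals <- num
    colnames(vals) <- colnames(tab)[-1]
  }
  rownames(vals) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  meta <- meta[meta$sample_id %in% colnames(vals), , drop = FALSE]
  expression_matrix(vals, meta, scale_tag = scale_tag)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#' @param x An `expr_matrix`.
#' @param path Matrix TSV path.
#' @param metadata_path Optional metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$samples, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-species, per-tissue mean expression
#'
#' Averages replicates of each species within one tissue on the log scale.
#' Masked cells propagate: a species whose samples are all masked stays
#' masked in the output.
#'
#' @param x An `expr_matrix` on the `log2_tmm_rpkm` scale.
#' @param tissue Tissue label to aggregate.
#' @return Gene x species numeric matrix (`NA` = masked).
#' @export
species_mean <- function(x, tissue) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- x$samples$tissue == tissue
  if (!any(keep)) stop("tissue not found: ", tissue)
  sp <- x$samples$species[keep]
  vals <- x$values[, keep, drop = FALSE]
  out <- vapply(unique(sp), function(s) {
    cols <- which(sp == s)
    rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(vals)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(vals))
  dimnames(out) <- list(rownames(vals), unique(sp))
  out[is.nan(out)] <- NA_real_
  out
}
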