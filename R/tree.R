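#' Read a rooted phylogeny from a Newick file
#'
#' Thin, validating wrapper around [ape::read.tree()].  Branch lengths are
#' expected in million years (Myr), matching the time-calibrated trees the
#' pipeline consumes.  Tip labels are normalized (spaces to underscores) so
#' that species names match expression and life-history tables exactly.
#'
#' @param path Path to a Newick file.
#' @param ultrametric_tol Relative tolerance used when checking (and
#'   recording) whether the tree is ultrametric.
#' @return An object of class `phylo` with an `ultrametric` attribute.
#' @export
read_newick <- function(path, ultrametric_tol = 1e-6) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_phylogeny(tr)
  tr$tip.label <- normalize_species(tr$tip.label)
  attr(tr, "ultrametric") <- ape::is.ultrametric(tr, tol = ultrametric_tol)
  tr
}

#' Write a phylogeny to Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

#' Normalize species names
#'
#' Species names are matched by exact string across the expression matrix,
#' the life-history table and the tree after a single documented
#' normalization: whitespace runs become underscores.  Mismatches downstream
#' are errors, never silent drops.
#' @param x Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) gsub("\\s+", "_", trimws(as.character(x)))

#' Prune a phylogeny to a taxon subset
#'
#' Retained root-to-tip path lengths are preserved, so Brownian-motion
#' covariances built after pruning equal sub-blocks of the full covariance.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 0) stop("empty taxa set")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Brownian-motion covariance from a phylogeny
#'
#' `C[i, j]` is the shared path length (Myr) from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' depths.  This is the error covariance (up to the rate sigma^2) of a trait
#' evolving by Brownian motion on the tree.
#'
#' @param tree A `phylo` object.
#' @param taxa Optional taxon subset; the tree is pruned first.
#' @return A symmetric positive semi-definite matrix with dimnames = taxa.
#' @export
bm_covariance <- function(tree, taxa = NULL) {
  if (!is.null(taxa)) tree <- prune_tree(tree, taxa)
  C <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) C <- C[taxa, taxa, drop = FALSE]
  C
}

#' Patristic distance matrix
#'
#' `d[i, j]` is the sum of branch lengths on the path between tips i and j.
#' For an ultrametric tree of depth T, `d[i, j] = 2 * (T - C[i, j])` where C
#' is the Brownian-motion covariance.
#'
#' @param tree A `phylo` object.
#' @return A symmetric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Stationary-root Ornstein-Uhlenbeck covariance
#'
#' For an ultrametric tree, the OU process with selection strength `alpha`
#' has tip covariance proportional to
#' `exp(-alpha * d[i,j]) * (1 - exp(-2 * alpha * C[i,j])) / (2 * alpha)`,
#' which tends to the Brownian-motion covariance C as `alpha -> 0` and to a
#' multiple of the identity as `alpha -> Inf`.
#'
#' @param C Brownian-motion covariance (from [bm_covariance()]).
#' @param d Patristic distances on the same taxa.
#' @param alpha Selection strength (1/Myr), > 0.
#' @return Covariance matrix (rate sigma^2 factored out).
#' @export
ou_covariance <- function(C, d, alpha) {
  stopifnot(alpha > 0, all(dim(C) == dim(d)))
  exp(-alpha * d) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}
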