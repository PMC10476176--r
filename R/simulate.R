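# Synthetic-data generators.  Every generator is a pure function of its
# parameters and seed; ground-truth labels are returned alongside the data so
# downstream calling steps can be scored without re-reading parameters.

#' Simulate an ultrametric species tree
#'
#' @param n_tips Number of tips (>= 3).
#' @param model `"birth-death"` (via [ape::rphylo()]) or `"coalescent"`
#'   (via [ape::rcoal()]).
#' @param depth Root-to-tip depth the tree is rescaled to, in Myr.  The
#'   default 150 matches the span of the mammalian radiation the pipeline
#'   targets.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, model = c("birth-death", "coalescent"),
                          depth = 150, seed = 1L) {
  model <- match.arg(model)
  if (n_tips < 3) stop("n_tips must be >= 3")
  set.seed(seed)
  tr <- switch(model,
    "birth-death" = ape::rphylo(n_tips, birth = 0.2, death = 0.05),
    "coalescent"  = ape::rcoal(n_tips))
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  cur <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length * depth / cur
  attr(tr, "ultrametric") <- TRUE
  tr
}

# Draw one Brownian-motion realization at the tips: sd = tip standard
# deviation at the root-to-tip depth (not the per-Myr rate).
rbm_tips <- function(tree, sd = 1, C = NULL) {
  if (is.null(C)) C <- ape::vcv.phylo(tree)
  depth <- max(diag(C))
  L <- chol(C / depth)
  drop(crossprod(L, stats::rnorm(nrow(C)))) * sd
}

#' Simulate allometrically structured life-history traits
#'
#' log AW evolves by Brownian motion on the tree; log ML and log FTM follow
#' allometric lines in log AW plus BM-distributed residuals whose tip
#' standard deviation is `bm_sigma`.  ML and FTM residuals can be correlated
#' (`res_cor`), which is what makes the two longevity traits correlated
#' beyond their shared weight dependence.
#'
#' @param tree Ultrametric `phylo`.
#' @param allometric_slope Slopes of log trait on log AW,
#'   `c(ML = , FTM = )`.
#' @param allometric_intercept Intercepts on the natural-log scale.
#' @param bm_sigma Tip sd of the BM residuals (natural-log units).
#' @param aw_log_mean,aw_log_sd Mean and tip sd of log AW (g).
#' @param res_cor Correlation between ML and FTM residuals.
#' @param seed Integer seed.
#' @return `list(table = life_history, truth = data.frame)`; `truth` holds
#'   the residuals and parameters actually drawn.
#' @export
simulate_life_history <- function(tree,
                                  allometric_slope = c(ML = 0.2, FTM = 0.25),
                                  allometric_intercept = c(ML = 1.8, FTM = -1.5),
                                  bm_sigma = 0.4,
                                  aw_log_mean = log(1000), aw_log_sd = 2,
                                  res_cor = 0.7, seed = 1L) {
  if (!all(is.finite(c(allometric_slope, allometric_intercept, bm_sigma))))
    stop("non-finite parameters")
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  set.seed(seed)
  C <- ape::vcv.phylo(tree)
  sp <- rownames(C)
  log_aw <- aw_log_mean + rbm_tips(tree, sd = aw_log_sd, C = C)
  res <- matrix(0, length(sp), 2, dimnames = list(sp, c("ML", "FTM")))
  if (bm_sigma > 0) {
    z1 <- rbm_tips(tree, sd = 1, C = C)
    z2 <- rbm_tips(tree, sd = 1, C = C)
    res[, "ML"] <- bm_sigma * z1
    res[, "FTM"] <- bm_sigma * (res_cor * z1 + sqrt(1 - res_cor^2) * z2)
  }
  log_ml <- allometric_intercept["ML"] + allometric_slope["ML"] * log_aw + res[, "ML"]
  log_ftm <- allometric_intercept["FTM"] + allometric_slope["FTM"] * log_aw + res[, "FTM"]
  tab <- as_life_history(data.frame(
    species = sp, AW = exp(log_aw), ML = exp(log_ml), FTM = exp(log_ftm),
    stringsAsFactors = FALSE))
  truth <- data.frame(species = sp, log_AW = log_aw, log_ML = log_ml,
                      log_FTM = log_ftm, res_ML = res[, "ML"],
                      res_FTM = res[, "FTM"], seed = seed,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Inject missingness into life-history traits
#'
#' Emulates the three mechanisms used to benchmark trait imputation:
#' `MCAR` deletes cells uniformly; `MAR_AW` splits species at the median
#' adult weight and allocates the missing cells between the small- and
#' large-weight groups per `split_weights` (defaults: ML 82.43% / 17.57%,
#' FTM 62.34% / 37.66%, small-weight species losing more); `MAR_HD` splits
#' at half the maximum patristic distance to a reference species (data are
#' scarcer for species far from well-studied ones).
#'
#' @param tab `life_history` table.
#' @param mechanism `"MCAR"`, `"MAR_AW"` or `"MAR_HD"`.
#' @param proportion Overall fraction of target cells to delete, in
#'   `[0, 0.9]`.
#' @param traits Trait columns subjected to deletion.
#' @param split_weights Named list per trait, `c(more, less)` fractions of
#'   missing cells in the (small-weight / far-from-reference) vs other
#'   group.
#' @param tree Required for `MAR_HD`.
#' @param reference_species Reference tip for `MAR_HD`; defaults to a tip
#'   matching "homo" or "human" (case-insensitive), else the first tip
#'   alphabetically.
#' @param seed Integer seed.
#' @return The table with deleted cells set `NA` and status columns set to
#'   `"missing"`; the deletion mask is attached as attribute `"deleted"`.
#' @export
inject_missingness <- function(tab, mechanism = c("MCAR", "MAR_AW", "MAR_HD"),
                               proportion,
                               traits = c("ML", "FTM"),
                               split_weights = list(ML = c(0.8243, 0.1757),
                                                    FTM = c(0.6234, 0.3766)),
                               tree = NULL, reference_species = NULL,
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (proportion < 0 || proportion > 0.9) stop("proportion must be in [0, 0.9]")
  tab <- as_life_history(tab)
  set.seed(seed)
  n <- nrow(tab)
  deleted <- matrix(FALSE, n, length(traits), dimnames = list(tab$species, traits))
  if (proportion > 0) {
    group_hi <- switch(mechanism,
      MCAR = NULL,
      MAR_AW = tab$AW < stats::median(tab$AW),
      MAR_HD = {
        if (is.null(tree)) stop("MAR_HD needs a tree")
        d <- patristic_distances(prune_tree(tree, tab$species))
        ref <- reference_species
        if (is.null(ref)) {
          hit <- grep("homo|human", tab$species, ignore.case = TRUE, value = TRUE)
          ref <- if (length(hit)) hit[1] else sort(tab$species)[1]
        }
        d[tab$species, ref] > max(d[, ref]) / 2
      })
    for (tr in traits) {
      m <- round(proportion * n)
      if (m == 0) next
      if (is.null(group_hi)) {
        idx <- sample.int(n, m)
      } else {
        w <- split_weights[[tr]]
        if (is.null(w)) w <- c(0.5, 0.5)
        hi <- which(group_hi); lo <- which(!group_hi)
        m_hi <- min(round(m * w[1] / sum(w)), length(hi))
        m_lo <- min(m - m_hi, length(lo))
        idx <- c(sample(hi, m_hi), sample(lo, m_lo))
      }
      deleted[idx, tr] <- TRUE
      tab[[tr]][idx] <- NA_real_
      tab[[paste0(tr, "_status")]][idx] <- "missing"
    }
  }
  attr(tab, "deleted") <- deleted
  tab
}

#' Simulate a species-level log-expression matrix tracking a trait
#'
#' A configurable fraction of genes is linearly associated with the given
#' trait; residual variation around the gene's line is drawn iid, by
#' Brownian motion on the tree, or by a stationary Ornstein-Uhlenbeck
#' process.  Each gene's ortholog set is thinned to `presence_rate`
#' (species where the gene is absent are masked, not zero), and
#' `n_replicates` samples per species add within-species noise `rep_sd`
#' (not described for the real data, hence an explicit parameter).
#'
#' @param tree Ultrametric `phylo`.
#' @param trait_vector Named numeric trait (tips of `tree`), e.g. log2 ML.
#' @param n_genes Number of genes.
#' @param frac_associated Fraction of genes with true slopes.
#' @param slope_range `c(lo, hi)` of absolute true slopes; signs random.
#' @param residual_model `"iid"`, `"BM"` or `"OU"`.
#' @param residual_sd Tip sd of gene residuals.
#' @param ou_alpha OU selection strength (1/Myr) when `residual_model="OU"`.
#' @param presence_rate Per-species ortholog retention probability.
#' @param min_present Floor on present species per gene.
#' @param n_replicates Samples per species.
#' @param rep_sd Within-species replicate sd.
#' @param tissue Tissue label written into the sample table.
#' @param base_mean Mean baseline expression (log2 scale).
#' @param seed Integer seed.
#' @return `list(expr = expr_matrix, truth = data.frame)` where `truth` has
#'   one row per gene (associated flag, true slope, residual model).
#' @export
simulate_expression <- function(tree, trait_vector, n_genes = 200,
                                frac_associated = 0.1,
                                slope_range = c(0.3, 0.8),
                                residual_model = c("iid", "BM", "OU"),
                                residual_sd = 0.5, ou_alpha = 0.02,
                                presence_rate = 1, min_present = 6,
                                n_replicates = 2, rep_sd = 0.25,
                                tissue = "liver", base_mean = 5, seed = 1L) {
  residual_model <- match.arg(residual_model)
  if (frac_associated < 0 || frac_associated > 1)
    stop("frac_associated must be in [0, 1]")
  sp <- tree$tip.label
  if (!all(sp %in% names(trait_vector)))
    stop("trait_vector must cover all tips")
  trait <- trait_vector[sp]
  n_sp <- length(sp)
  set.seed(seed)
  C <- ape::vcv.phylo(tree)[sp, sp]
  depth <- max(diag(C))
  Lres <- switch(residual_model,
    iid = NULL,
    BM = chol(C / depth),
    OU = {
      d <- patristic_distances(tree)[sp, sp]
      V <- ou_covariance(C, d, ou_alpha)
      chol(V / mean(diag(V)))
    })
  n_assoc <- round(frac_associated * n_genes)
  assoc <- rep(c(TRUE, FALSE), c(n_assoc, n_genes - n_assoc))
  slope <- ifelse(assoc,
                  sample(c(-1, 1), n_genes, replace = TRUE) *
                    stats::runif(n_genes, slope_range[1], slope_range[2]),
                  0)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  mu <- matrix(0, n_genes, n_sp, dimnames = list(gene_ids, sp))
  for (g in seq_len(n_genes)) {
    z <- stats::rnorm(n_sp)
    res <- if (is.null(Lres)) z * residual_sd else
      drop(crossprod(Lres, z)) * residual_sd
    mu[g, ] <- base_mean + slope[g] * (trait - mean(trait)) + res
  }
  presence <- matrix(stats::runif(n_genes * n_sp) < presence_rate,
                     n_genes, n_sp, dimnames = list(gene_ids, sp))
  for (g in seq_len(n_genes)) {
    k <- sum(presence[g, ])
    if (k < min_present) {
      add <- sample(which(!presence[g, ]), min_present - k)
      presence[g, add] <- TRUE
    }
  }
  sample_ids <- as.vector(t(outer(sp, seq_len(n_replicates),
                                  function(s, r) paste0(s, "_r", r))))
  vals <- matrix(NA_real_, n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (r in seq_len(n_replicates)) {
    cols <- seq(r, by = n_replicates, length.out = n_sp)
    noise <- matrix(stats::rnorm(n_genes * n_sp, sd = rep_sd), n_genes, n_sp)
    block <- mu + noise
    block[!presence] <- NA_real_
    vals[, cols] <- block
  }
  samples <- data.frame(
    sample_id = sample_ids,
    species = rep(sp, each = n_replicates),
    tissue = tissue,
    replicate = rep(seq_len(n_replicates), times = n_sp),
    batch = "sim", stringsAsFactors = FALSE)
  truth <- data.frame(gene = gene_ids, associated = assoc, true_slope = slope,
                      residual_model = residual_model,
                      residual_sd = residual_sd,
                      ou_alpha = ifelse(residual_model == "OU", ou_alpha, NA),
                      n_present = rowSums(presence), seed = seed,
                      stringsAsFactors = FALSE)
  expr <- expression_matrix(vals, samples, scale_tag = "log2_tmm_rpkm",
                            presence = presence)
  list(expr = expr, truth = truth)
}

#' Simulate fragment counts from a log-expression matrix
#'
#' Count expectation is proportional to
#' `2^log_expression * gene_length * library_size` (scaled by `scale_const`
#' so a round trip through RPKM recovers the input magnitudes); noise is
#' negative-binomial with the given dispersion, collapsing to Poisson at
#' dispersion 0.  Masked cells stay masked.
#'
#' @param log_expression `expr_matrix` on the log2 scale.
#' @param library_sizes Named per-sample library sizes (fragments).
#' @param gene_lengths Named per-gene lengths (bp).
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param scale_const Multiplier on the expectation (default 1e-9, the
#'   RPKM convention inverted).
#' @param seed Integer seed.
#' @return An `expr_matrix` of counts.
#' @export
simulate_counts <- function(log_expression, library_sizes, gene_lengths,
                            dispersion = 0.05, scale_const = 1e-9, seed = 1L) {
  stopifnot(inherits(log_expression, "expr_matrix"))
  x <- log_expression$values
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  lib <- library_sizes[colnames(x)]
  len <- gene_lengths[rownames(x)]
  if (anyNA(lib)) stop("library_sizes must cover all samples")
  if (anyNA(len)) stop("gene_lengths must cover all genes")
  set.seed(seed)
  mu <- (2^x) * outer(len, lib) * scale_const
  cnt <- mu
  obs <- !is.na(mu)
  cnt[obs] <- if (dispersion > 0)
    stats::rnbinom(sum(obs), mu = mu[obs], size = 1 / dispersion)
  else stats::rpois(sum(obs), mu[obs])
  expression_matrix(cnt, log_expression$samples, scale_tag = "counts",
                    presence = log_expression$presence)
}

#' Simulate a selection-intensity (k) table coupled to expression direction
#'
#' Produces per-gene relaxation parameters k (log-normal) whose log is
#' shifted by `coupling * sign(true slope) * shift` for trait-associated
#' genes, so `coupling = 1` aligns intensified selection (k > 1) with
#' positive association and relaxed selection (k < 1) with negative
#' association.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param coupling In `[-1, 1]`.
#' @param log_k_sd Sd of log k noise.
#' @param shift Mean |log k| displacement at |coupling| = 1.
#' @param seed Integer seed.
#' @return data.frame with `gene`, `k`, `p`, `omega1`, `omega2`, `omega3`.
#' @export
simulate_selection_table <- function(truth, coupling = 0, log_k_sd = 0.5,
                                     shift = 1, seed = 1L) {
  if (coupling < -1 || coupling > 1) stop("coupling must be in [-1, 1]")
  set.seed(seed)
  n <- nrow(truth)
  dir <- sign(truth$true_slope)
  log_k <- coupling * dir * shift + stats::rnorm(n, sd = log_k_sd)
  k <- exp(log_k)
  p <- stats::pchisq((log_k / log_k_sd)^2, df = 1, lower.tail = FALSE)
  data.frame(gene = truth$gene, k = k, p = p,
             omega1 = stats::runif(n, 0.01, 0.5),
             omega2 = 1,
             omega3 = stats::runif(n, 1, 5),
             stringsAsFactors = FALSE)
}
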