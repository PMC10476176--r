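# Two-step robust P values and the Westfall-Young maxT permutation
# adjustment.
#
# Step 1: fit on all species where the gene exists, remove the single
# species with the largest absolute raw residual (the potential outlier),
# refit -> P_robust.  Step 2: from the step-1 species set, remove one
# remaining species at a time, refit, and take the largest (least
# significant) P as P_max.  The residual model is re-selected at every refit
# by default.
#
# Family-wise adjustment permutes the trait across the species panel (the
# same permutations for every gene, preserving inter-gene dependence),
# recomputes the two robust statistics per gene per permutation with the
# per-gene model held at its observed choice, and applies step-down maxT.

#' Two-step robust P values for one gene
#'
#' @param y Named species-mean expression (`NA` = masked species).
#' @param x Named trait values.
#' @param tree `phylo` covering the species.
#' @param models Candidate residual models.
#' @param floor_n Minimum species; below it the gene is skipped with a
#'   reason, not an error.
#' @param reselect Re-select the model at each refit (default); `FALSE`
#'   holds the full-data model fixed.
#' @param criterion Model-selection criterion, see [select_model()].
#' @return A list: `p_raw`, `p_robust`, `p_max`, `dropped` (step-1 species),
#'   `model`/`alpha` (step-1 refit), `slope`, `n`, `loo_p` (named step-2 P
#'   values), or `list(skipped = TRUE, reason = ...)`.
#' @export
robust_pvalues <- function(y, x, tree, models = c("OLS", "BM", "OU"),
                           floor_n = 6, reselect = TRUE,
                           criterion = "AIC") {
  al <- .align_xy(y, x)
  taxa <- intersect(al$taxa, tree$tip.label)
  if (length(taxa) < floor_n)
    return(list(skipped = TRUE, n = length(taxa),
                reason = sprintf("only %d species (floor %d)",
                                 length(taxa), floor_n)))
  yv <- al$y[taxa]; xv <- al$x[taxa]
  C <- bm_covariance(tree, taxa)
  d <- patristic_distances(prune_tree(tree, taxa))[taxa, taxa]
  full <- .fit_gene(yv, xv, C, d, models, criterion)
  res <- yv - (full$best$intercept + full$best$slope * xv)
  dropped <- taxa[which.max(abs(res))]
  s1 <- setdiff(taxa, dropped)
  refit <- function(keep) {
    if (reselect)
      .fit_gene(yv[keep], xv[keep], C[keep, keep], d[keep, keep],
                models, criterion)$best
    else switch(full$best$model,
      OLS = .as_fit_result(.fit_core(yv[keep], xv[keep]), "OLS", 3),
      BM  = .fit_bm(yv[keep], xv[keep], C[keep, keep]),
      OU  = .fit_ou(yv[keep], xv[keep], C[keep, keep], d[keep, keep]))
  }
  f1 <- refit(s1)
  loo_p <- vapply(s1, function(s) refit(setdiff(s1, s))$p, numeric(1))
  list(skipped = FALSE, p_raw = full$best$p, p_robust = f1$p,
       p_max = max(loo_p), dropped = dropped, model_full = full$best$model,
       model = f1$model, alpha = f1$alpha, slope = f1$slope,
       intercept = f1$intercept, n = length(taxa), loo_p = loo_p)
}

# Fast quadratic-form engine: for one gene (fixed covariance inverse A) and
# a matrix XM of trait columns (observed + permuted), return the step-1
# robust |t| and the step-2 min |t| over leave-one-out deletions, for every
# column.  Uses the Schur-complement identity
#   (V[-s,-s])^-1 = A[-s,-s] - A[-s,s] A[s,-s] / A[s,s]
# so every single-species deletion costs O(n) given full-set products.
.robust_stats_engine <- function(y, XM, A, do_min = TRUE) {
  n <- length(y); m <- ncol(XM)
  one <- rep(1, n)
  w1 <- drop(A %*% one); wy <- drop(A %*% y); WX <- A %*% XM
  dA <- diag(A)
  s11 <- sum(w1); s1y <- sum(wy); syy <- sum(y * wy)
  s1x <- colSums(WX); sxy <- colSums(y * WX); sxx <- colSums(XM * WX)
  D <- s11 * sxx - s1x^2
  b <- (s11 * sxy - s1x * s1y) / D
  a <- (s1y - b * s1x) / s11
  R <- y - matrix(a, n, m, byrow = TRUE) - XM * matrix(b, n, m, byrow = TRUE)
  sidx <- max.col(t(abs(R)), ties.method = "first")
  ii <- cbind(sidx, seq_len(m))
  y_s <- y[sidx]; x_s <- XM[ii]
  w1_s <- w1[sidx]; wy_s <- wy[sidx]; wx_s <- WX[ii]; Ass <- dA[sidx]
  g1 <- w1_s - Ass; gy <- wy_s - y_s * Ass; gx <- wx_s - x_s * Ass
  q11 <- s11 - 2 * w1_s + Ass - g1^2 / Ass
  q1y <- s1y - wy_s - w1_s * y_s + Ass * y_s - g1 * gy / Ass
  q1x <- s1x - wx_s - w1_s * x_s + Ass * x_s - g1 * gx / Ass
  qyy <- syy - 2 * y_s * wy_s + Ass * y_s^2 - gy^2 / Ass
  qxy <- sxy - y_s * wx_s - wy_s * x_s + Ass * y_s * x_s - gy * gx / Ass
  qxx <- sxx - 2 * x_s * wx_s + Ass * x_s^2 - gx^2 / Ass
  tstat_from <- function(q11, q1y, q1x, qyy, qxy, qxx, df) {
    D <- q11 * qxx - q1x^2
    b <- (q11 * qxy - q1x * q1y) / D
    a <- (q1y - b * q1x) / q11
    rss <- pmax(qyy - a * q1y - b * qxy, 0)
    se2 <- rss / df * q11 / D
    tv <- abs(b) / sqrt(se2)
    tv[!is.finite(tv) | D <= 0] <- 0
    tv
  }
  t_rob <- tstat_from(q11, q1y, q1x, qyy, qxy, qxx, n - 3)
  t_min <- rep(NA_real_, m)
  if (do_min) for (j in seq_len(m)) {
    s <- sidx[j]
    colA <- A[, s]
    w1p <- w1 - colA * (1 + g1[j] / Ass[j])
    wyp <- wy - colA * (y_s[j] + gy[j] / Ass[j])
    wxp <- WX[, j] - colA * (x_s[j] + gx[j] / Ass[j])
    dAp <- dA - colA^2 / Ass[j]
    r <- seq_len(n)[-s]
    yr <- y[r]; xr <- XM[r, j]
    w1r <- w1p[r]; wyr <- wyp[r]; wxr <- wxp[r]; dAr <- dAp[r]
    G1 <- w1r - dAr; Gy <- wyr - yr * dAr; Gx <- wxr - xr * dAr
    tt <- tstat_from(
      q11[j] - 2 * w1r + dAr - G1^2 / dAr,
      q1y[j] - wyr - w1r * yr + dAr * yr - G1 * Gy / dAr,
      q1x[j] - wxr - w1r * xr + dAr * xr - G1 * Gx / dAr,
      qyy[j] - 2 * yr * wyr + dAr * yr^2 - Gy^2 / dAr,
      qxy[j] - yr * wxr - wyr * xr + dAr * xr * yr - Gy * Gx / dAr,
      qxx[j] - 2 * xr * wxr + dAr * xr^2 - Gx^2 / dAr,
      n - 4)
    t_min[j] <- min(tt)
  }
  list(t_robust = t_rob, t_min = t_min, dropped = sidx)
}

#' Westfall-Young maxT adjustment of the robust statistics
#'
#' Permutes the trait across species `n_perm` times (one shared set of
#' permutations for all genes), recomputes the step-1 robust |t| and the
#' step-2 minimum leave-one-out |t| per gene per permutation with the
#' per-gene residual model fixed at its observed choice, and converts each
#' observed statistic into a step-down family-wise adjusted P.
#'
#' @param expr Gene x species matrix of species-mean expression (`NA` =
#'   masked).
#' @param trait Named trait vector.
#' @param tree `phylo`.
#' @param gene_models Named character vector (per gene) in
#'   `c("OLS", "BM", "OU")`; defaults to `"BM"` for all genes.
#' @param gene_alphas Named numeric vector of OU alphas (used where
#'   `gene_models == "OU"`).
#' @param n_perm Number of trait permutations (a warning below 100).
#' @param seed Integer seed for the shared permutations.
#' @param floor_n Genes observed in fewer species are returned with `NA`.
#' @param statistics `"both"` (default) or `"robust"` to skip the step-2
#'   minimum statistic (its leave-one-out chain is the expensive part).
#' @return data.frame: `gene`, `t_robust`, `t_min`, `p_robust_perm`,
#'   `p_max_perm` (per-gene permutation P), `p_robust_adj`, `p_max_adj`
#'   (step-down maxT).
#' @export
adjust_pvalues <- function(expr, trait, tree, gene_models = NULL,
                           gene_alphas = NULL, n_perm = 1000, seed = 1L,
                           floor_n = 6, statistics = c("both", "robust")) {
  statistics <- match.arg(statistics)
  if (n_perm < 100) warning("n_perm < 100 gives coarse adjusted P values")
  genes <- rownames(expr)
  species <- colnames(expr)
  trait <- trait[species]
  if (anyNA(trait)) stop("trait must be observed for every expression species")
  if (is.null(gene_models)) gene_models <- stats::setNames(rep("BM", length(genes)), genes)
  set.seed(seed)
  P <- n_perm
  perm_idx <- replicate(P, sample.int(length(species)))
  C_full <- bm_covariance(tree, species)
  d_full <- patristic_distances(prune_tree(tree, species))[species, species]
  T_rob <- matrix(NA_real_, length(genes), P + 1)
  T_min <- matrix(NA_real_, length(genes), P + 1)
  for (gi in seq_along(genes)) {
    yv <- expr[gi, ]
    keep <- which(!is.na(yv))
    if (length(keep) < floor_n) next
    XM <- cbind(trait[keep], matrix(trait[perm_idx], ncol = P)[keep, , drop = FALSE])
    V <- switch(gene_models[[genes[gi]]],
      OLS = diag(length(keep)),
      BM  = C_full[keep, keep],
      OU  = ou_covariance(C_full[keep, keep], d_full[keep, keep],
                          gene_alphas[[genes[gi]]]))
    A <- chol2inv(chol(V))
    st <- .robust_stats_engine(yv[keep], XM, A,
                               do_min = statistics == "both")
    T_rob[gi, ] <- st$t_robust
    T_min[gi, ] <- st$t_min
  }
  do_min <- statistics == "both"
  out <- data.frame(gene = genes,
                    t_robust = T_rob[, 1], t_min = T_min[, 1],
                    p_robust_perm = .perm_p(T_rob),
                    p_max_perm = if (do_min) .perm_p(T_min) else NA_real_,
                    p_robust_adj = .maxT(T_rob),
                    p_max_adj = if (do_min) .maxT(T_min) else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Per-gene (unadjusted) permutation P: share of permuted |t| >= observed.
.perm_p <- function(T) {
  obs <- T[, 1]; perm <- T[, -1, drop = FALSE]
  P <- ncol(perm)
  p <- (1 + rowSums(perm >= obs, na.rm = TRUE)) / (P + 1)
  p[is.na(obs)] <- NA_real_
  p
}

# Step-down maxT adjusted P values (Westfall & Young free step-down).
.maxT <- function(T) {
  obs <- T[, 1]; perm <- T[, -1, drop = FALSE]
  P <- ncol(perm)
  ok <- which(!is.na(obs))
  if (length(ok) == 0) return(rep(NA_real_, length(obs)))
  ord <- ok[order(obs[ok], decreasing = TRUE)]
  cmax <- rep(-Inf, P)
  praw <- numeric(length(ord))
  for (i in rev(seq_along(ord))) {
    cmax <- pmax(cmax, perm[ord[i], ])
    praw[i] <- (1 + sum(cmax >= obs[ord[i]])) / (P + 1)
  }
  padj <- cummax(praw)
  out <- rep(NA_real_, length(obs))
  out[ord] <- padj
  out
}

#' Run the per-gene association pipeline for several longevity traits
#'
#' For each trait: log2-scale absolute traits (ML, FTM), use allometric
#' residual traits as-is, run [robust_pvalues()] per gene, then adjust both
#' robust statistics by [adjust_pvalues()] (maxT; `adjust = "BH"` falls back
#' to Benjamini-Hochberg on the raw P values).
#'
#' @param expr Gene x species matrix of species-mean expression.
#' @param life `life_history` table (residual traits are computed when
#'   absent).
#' @param tree `phylo`.
#' @param traits Subset of `c("ML", "FTM", "MLres", "FTMres")`.
#' @param tissue Label copied into the records.
#' @param models Candidate residual models.
#' @param n_perm Permutations for maxT.
#' @param seed Integer seed.
#' @param floor_n Minimum species per gene.
#' @param adjust `"maxT"` or `"BH"`.
#' @param criterion Model-selection criterion.
#' @return data.frame of association records (one row per gene x trait).
#' @export
pgls_pipeline <- function(expr, life, tree,
                          traits = c("ML", "FTM", "MLres", "FTMres"),
                          tissue = "liver", models = c("OLS", "BM", "OU"),
                          n_perm = 500, seed = 1L, floor_n = 6,
                          adjust = c("maxT", "BH"), criterion = "AIC") {
  adjust <- match.arg(adjust)
  life <- as_life_history(life)
  if (any(c("MLres", "FTMres") %in% traits) && is.null(life$MLres))
    life <- allometric_residuals(life)
  records <- list()
  for (tr in traits) {
    xv <- if (tr %in% c("ML", "FTM")) log2(life[[tr]]) else life[[tr]]
    names(xv) <- life$species
    xv <- xv[!is.na(xv)]
    sp <- intersect(intersect(colnames(expr), names(xv)), tree$tip.label)
    if (length(sp) < floor_n) stop("too few species with trait ", tr)
    ex <- expr[, sp, drop = FALSE]
    rb <- lapply(seq_len(nrow(ex)), function(gi)
      robust_pvalues(ex[gi, ], xv[sp], tree, models = models,
                     floor_n = floor_n, criterion = criterion))
    names(rb) <- rownames(ex)
    keep <- !vapply(rb, `[[`, logical(1), "skipped")
    rec <- data.frame(
      gene = rownames(ex), tissue = tissue, trait = tr,
      model = NA_character_, slope = NA_real_, n = NA_integer_,
      dropped = NA_character_, p_raw = NA_real_, p_robust = NA_real_,
      p_max = NA_real_, p_robust_adj = NA_real_, p_max_adj = NA_real_,
      skipped = !keep, stringsAsFactors = FALSE)
    for (f in c("model", "dropped")) rec[[f]][keep] <-
      vapply(rb[keep], `[[`, "", f)
    for (f in c("slope", "p_raw", "p_robust", "p_max")) rec[[f]][keep] <-
      vapply(rb[keep], `[[`, numeric(1), f)
    rec$n[keep] <- vapply(rb[keep], `[[`, numeric(1), "n")
    if (adjust == "maxT") {
      gm <- stats::setNames(rec$model, rec$gene)
      ga <- stats::setNames(vapply(rb, function(r)
        if (isTRUE(r$skipped)) NA_real_ else r$alpha, numeric(1)), rec$gene)
      adj <- adjust_pvalues(ex, xv[sp], tree, gene_models = gm,
                            gene_alphas = ga, n_perm = n_perm,
                            seed = seed + match(tr, traits),
                            floor_n = floor_n)
      rec$p_robust_adj <- adj$p_robust_adj[match(rec$gene, adj$gene)]
      rec$p_max_adj <- adj$p_max_adj[match(rec$gene, adj$gene)]
    } else {
      rec$p_robust_adj <- stats::p.adjust(rec$p_robust, "BH")
      rec$p_max_adj <- stats::p.adjust(rec$p_max, "BH")
    }
    records[[tr]] <- rec
  }
  do.call(rbind, c(records, list(make.row.names = FALSE)))
}

#' Call longevity-correlated genes from association records
#'
#' A gene is significant for one trait when both adjusted cutoffs are met
#' strictly (`p_robust_adj < 0.005` and `p_max_adj < 0.05` by default), and
#' longevity-correlated when significant for at least `min_traits` of the
#' longevity traits.  Direction is the majority slope sign over significant
#' traits; exact sign conflicts are flagged.
#'
#' @param records Output of [pgls_pipeline()].
#' @param p_robust_cut,p_max_cut Adjusted-P cutoffs (strict `<`).
#' @param min_traits Traits required (default 2).
#' @return data.frame: `gene`, `n_sig_traits`, `sig_traits`,
#'   `longevity_correlated`, `direction` (`"positive"`, `"negative"` or
#'   `"conflict"`).
#' @export
call_longevity_genes <- function(records, p_robust_cut = 0.005,
                                 p_max_cut = 0.05, min_traits = 2) {
  sig <- !is.na(records$p_robust_adj) & !is.na(records$p_max_adj) &
    records$p_robust_adj < p_robust_cut & records$p_max_adj < p_max_cut
  records$sig <- sig
  out <- do.call(rbind, lapply(split(records, records$gene), function(df) {
    s <- df[df$sig, , drop = FALSE]
    dir <- if (nrow(s) == 0) NA_character_ else {
      sgn <- sign(s$slope)
      if (all(sgn > 0)) "positive" else if (all(sgn < 0)) "negative"
      else if (sum(sgn > 0) > sum(sgn < 0)) "positive"
      else if (sum(sgn < 0) > sum(sgn > 0)) "negative" else "conflict"
    }
    data.frame(gene = df$gene[1], n_sig_traits = nrow(s),
               sig_traits = paste(s$trait, collapse = ","),
               longevity_correlated = nrow(s) >= min_traits,
               direction = dir, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene), ]
}
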