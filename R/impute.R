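# Phylogeny-aware imputation of life-history traits and its evaluation
# harness.  The imputer models the (log) traits jointly as multivariate
# normal with covariance (between-trait covariance R) x (Brownian-motion
# tree correlation) plus trait-specific iid noise, estimates the parameters
# by (restricted) maximum likelihood, and fills missing cells with their
# conditional expectation given every observed cell.

#' Principal-coordinate eigenvectors of a distance matrix
#'
#' Classical scaling of the double-centered squared-distance matrix;
#' axes with non-positive eigenvalues (tree metrics need not be Euclidean)
#' are truncated and the retained-variance fraction recorded.
#'
#' @param distance_matrix Symmetric, zero-diagonal matrix.
#' @param n_vectors Number of leading axes requested (capped at N-1 and at
#'   the number of positive eigenvalues).
#' @return Matrix (rows = taxa) with attribute `"retained_variance"`.
#' @export
pcoa_eigenvectors <- function(distance_matrix, n_vectors) {
  D <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  k <- min(n_vectors, n - 1, sum(pos))
  if (k < 1) stop("no positive eigenvalues")
  vec <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(vec) <- rownames(D)
  colnames(vec) <- paste0("PCo", seq_len(k))
  attr(vec, "retained_variance") <-
    sum(eig$values[seq_len(k)]) / sum(eig$values[pos])
  attr(vec, "eigenvalues") <- eig$values
  vec
}

#' Phylogenetic (Brownian-motion) trait imputation
#'
#' Traits are log-transformed, modeled jointly as
#' `vec(Y) ~ N(mu, R (x) Ctree + diag(noise) (x) I)` with `Ctree` the
#' depth-scaled BM correlation, parameters estimated by REML (default) or
#' ML, and missing cells replaced by their conditional means.  Observed
#' cells are returned untouched and status columns record `"imputed"`.
#'
#' @param tree `phylo` covering every species in the table.
#' @param tab `life_history` table with missing cells as `NA`.
#' @param traits Trait columns modeled jointly.
#' @param method `"REML"` or `"ML"`.
#' @param log_transform Model on the log scale (default) and
#'   back-transform.
#' @param maxit Optimizer iteration cap.
#' @return The completed `life_history` table; the fitted parameters are in
#'   attribute `"fit"`.
#' @export
bm_impute <- function(tree, tab, traits = c("AW", "ML", "FTM"),
                      method = c("REML", "ML"), log_transform = TRUE,
                      maxit = 400) {
  method <- match.arg(method)
  tab <- as_life_history(tab)
  traits <- intersect(traits, names(tab))
  sp <- tab$species
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  Y <- as.matrix(tab[, traits, drop = FALSE])
  rownames(Y) <- sp
  if (log_transform) Y <- log(Y)
  p <- ncol(Y); n <- nrow(Y)
  for (tr in traits)
    if (all(is.na(Y[, tr]))) stop("trait entirely missing: ", tr)
  if (!anyNA(Y)) return(tab)
  C <- bm_covariance(tree, sp)
  Ctree <- C / max(diag(C))
  obs <- !is.na(Y)
  # Parameters: lower-triangular Cholesky of R (log diagonal) + log noise sd.
  var0 <- apply(Y, 2, stats::var, na.rm = TRUE)
  L0 <- diag(sqrt(pmax(var0 * 0.7, 1e-4)), p)
  par0 <- c(L0[lower.tri(L0, diag = TRUE)], log(sqrt(pmax(var0 * 0.3, 1e-4))))
  di <- which(diag(p)[lower.tri(diag(p), diag = TRUE)] == 1)
  par0[di] <- log(par0[di])
  unpack <- function(par) {
    nL <- p * (p + 1) / 2
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- par[seq_len(nL)]
    diag(L) <- exp(diag(L))
    list(R = L %*% t(L), noise = exp(par[nL + seq_len(p)])^2)
  }
  yv <- as.vector(Y)          # trait-major: species within trait
  ov <- as.vector(obs)
  trait_of <- rep(seq_len(p), each = n)
  W <- outer(trait_of, seq_len(p), `==`) * 1
  W <- W[ov, , drop = FALSE]
  yo <- yv[ov]
  build_sigma <- function(th) {
    S <- kronecker(th$R, Ctree) + diag(rep(th$noise, each = n))
    S[ov, ov, drop = FALSE]
  }
  negll <- function(par) {
    th <- unpack(par)
    S <- build_sigma(th)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Si_y <- backsolve(ch, forwardsolve(t(ch), yo))
    Si_W <- backsolve(ch, forwardsolve(t(ch), W))
    XtSiX <- crossprod(W, Si_W)
    mu <- tryCatch(solve(XtSiX, crossprod(Si_W, yo)),
                   error = function(e) NULL)
    if (is.null(mu)) return(1e10)
    r <- yo - W %*% mu
    Si_r <- backsolve(ch, forwardsolve(t(ch), r))
    quad <- drop(crossprod(r, Si_r))
    ll <- -0.5 * (logdet + quad)
    if (method == "REML") ll <- ll - 0.5 * determinant(XtSiX)$modulus[1]
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
  th <- unpack(opt$par)
  S_full <- kronecker(th$R, Ctree) + diag(rep(th$noise, each = n))
  Soo <- S_full[ov, ov, drop = FALSE]
  ch <- chol(Soo)
  Si_W <- backsolve(ch, forwardsolve(t(ch), W))
  mu_hat <- solve(crossprod(W, Si_W), crossprod(Si_W, yo))
  mu_full <- mu_hat[trait_of]
  r <- yo - mu_full[ov]
  Si_r <- backsolve(ch, forwardsolve(t(ch), r))
  fill <- mu_full[!ov] + S_full[!ov, ov, drop = FALSE] %*% Si_r
  yv[!ov] <- fill
  Yhat <- matrix(yv, n, p, dimnames = list(sp, traits))
  if (log_transform) Yhat <- exp(Yhat)
  for (j in seq_len(p)) {
    tr <- traits[j]
    was_na <- is.na(tab[[tr]])
    tab[[tr]][was_na] <- Yhat[was_na, j]
    tab[[paste0(tr, "_status")]][was_na] <- "imputed"
  }
  attr(tab, "fit") <- list(R = th$R, noise = th$noise, mu = drop(mu_hat),
                           method = method, convergence = opt$convergence,
                           logLik = -opt$value)
  tab
}

#' Grand-mean imputation baseline
#' @param tab `life_history` table.
#' @param traits Traits to complete.
#' @param log_transform Mean on the log scale (default).
#' @return Completed table.
#' @export
mean_impute <- function(tab, traits = c("AW", "ML", "FTM"),
                        log_transform = TRUE) {
  tab <- as_life_history(tab)
  for (tr in intersect(traits, names(tab))) {
    v <- tab[[tr]]
    if (all(is.na(v))) stop("trait entirely missing: ", tr)
    m <- if (log_transform) exp(mean(log(v), na.rm = TRUE)) else
      mean(v, na.rm = TRUE)
    was_na <- is.na(v)
    tab[[tr]][was_na] <- m
    tab[[paste0(tr, "_status")]][was_na] <- "imputed"
  }
  tab
}

#' Predictive-mean-matching imputation baseline
#'
#' Regresses each incomplete (log) trait on the other observed traits and
#' optional covariates over complete cases, predicts for all species, and
#' copies the observed value of the donor with the nearest prediction.
#'
#' @param tab `life_history` table.
#' @param traits Traits to complete.
#' @param covariates Optional species x covariate matrix (e.g. PCoA
#'   eigenvectors), rownames = species.
#' @param log_transform Work on the log scale (default).
#' @return Completed table.
#' @export
pmm_impute <- function(tab, traits = c("AW", "ML", "FTM"),
                       covariates = NULL, log_transform = TRUE) {
  tab <- as_life_history(tab)
  traits <- intersect(traits, names(tab))
  Y <- as.matrix(tab[, traits, drop = FALSE])
  if (log_transform) Y <- log(Y)
  rownames(Y) <- tab$species
  X_extra <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[tab$species, , drop = FALSE]
  for (tr in traits) {
    y <- Y[, tr]
    if (!anyNA(y)) next
    preds <- Y[, setdiff(traits, tr), drop = FALSE]
    if (!is.null(X_extra)) preds <- cbind(preds, X_extra)
    pm <- rowMeans(preds, na.rm = TRUE)   # guard rows with missing predictors
    idx <- which(is.na(preds), arr.ind = TRUE)
    if (nrow(idx)) preds[idx] <- pm[idx[, 1]]
    cc <- !is.na(y)
    fit <- stats::lm.fit(cbind(1, preds[cc, , drop = FALSE]), y[cc])
    pred_all <- drop(cbind(1, preds) %*% fit$coefficients)
    donors <- which(cc)
    for (i in which(!cc)) {
      d <- donors[which.min(abs(pred_all[donors] - pred_all[i]))]
      Y[i, tr] <- y[d]
      val <- if (log_transform) exp(Y[i, tr]) else Y[i, tr]
      tab[[tr]][i] <- val
      tab[[paste0(tr, "_status")]][i] <- "imputed"
    }
  }
  tab
}

#' Normalized root-mean-square imputation error
#'
#' `sqrt(mean((Ximp - Xtrue)^2)) / (max(Xtrue) - min(Xtrue))`, evaluated
#' over originally-missing cells only, with the range taken over the true
#' values of the scored trait.  Computed on the (log) scale the imputer
#' worked on; as a ratio it is invariant to the log base.
#'
#' @param imputed Completed `life_history` table (status columns mark
#'   imputed cells).
#' @param truth Complete ground-truth table.
#' @param trait Trait column to score.
#' @param log_transform Score on the log scale (default).
#' @return Non-negative number.
#' @export
nrmse <- function(imputed, truth, trait = "ML", log_transform = TRUE) {
  st <- imputed[[paste0(trait, "_status")]]
  idx <- which(st == "imputed")
  xi <- imputed[[trait]][idx]
  xt <- truth[[trait]][match(imputed$species[idx], truth$species)]
  full_t <- truth[[trait]]
  if (log_transform) { xi <- log(xi); xt <- log(xt); full_t <- log(full_t) }
  rng <- max(full_t, na.rm = TRUE) - min(full_t, na.rm = TRUE)
  if (rng == 0) stop("zero range in true trait values")
  if (length(idx) == 0) return(0)
  sqrt(mean((xi - xt)^2)) / rng
}

#' Bias of the allometric slope after imputation
#'
#' `|slope(log trait ~ log AW, original data) - slope(imputed data)|`; a
#' sanity check that imputation preserves the biological signal, not just
#' pointwise accuracy.
#'
#' @param truth Complete table.
#' @param imputed Completed table.
#' @param trait Longevity trait regressed on AW (default `"ML"`).
#' @return Non-negative number.
#' @export
slope_bias <- function(truth, imputed, trait = "ML") {
  sl <- function(tb) {
    ok <- !is.na(tb$AW) & !is.na(tb[[trait]])
    if (sum(ok) < 3 || stats::var(log(tb$AW[ok])) == 0)
      stop("degenerate regression")
    unname(stats::coef(stats::lm(log(tb[[trait]][ok]) ~ log(tb$AW[ok])))[2])
  }
  abs(sl(truth) - sl(imputed))
}

#' Imputation benchmarking grid
#'
#' For every mechanism x missing-proportion x method x replicate: inject
#' missingness into the complete training table, impute, and score NRMSE
#' and slope bias against the original values.  The default proportion grid
#' is the 5-50% sweep used to benchmark the real data.
#'
#' @param train_table Complete `life_history` table.
#' @param tree `phylo` covering the table's species.
#' @param proportions Missing-proportion grid.
#' @param mechanisms Subset of `c("MCAR", "MAR_AW", "MAR_HD")`.
#' @param methods Subset of `c("phylo", "mean", "pmm")`.
#' @param reps Replicates per cell.
#' @param traits Traits deleted and scored.
#' @param n_pcoa If > 0, that many PCoA eigenvectors of the patristic
#'   distances are offered to the `pmm` method as covariates.
#' @param seed Integer seed.
#' @return data.frame with one row per (mechanism, proportion, method,
#'   replicate, trait) holding `nrmse` and `slope_bias`.
#' @export
evaluate_imputation <- function(train_table, tree,
                                proportions = c(0.05, 0.10, 0.15, 0.20,
                                                0.25, 0.30, 0.40, 0.50),
                                mechanisms = c("MCAR", "MAR_AW", "MAR_HD"),
                                methods = c("phylo", "mean", "pmm"),
                                reps = 10, traits = c("ML", "FTM"),
                                n_pcoa = 0, seed = 1L) {
  train_table <- as_life_history(train_table)
  if (anyNA(train_table[, c("AW", traits)])) stop("training table must be complete")
  covs <- if (n_pcoa > 0)
    pcoa_eigenvectors(patristic_distances(prune_tree(tree, train_table$species)),
                      n_pcoa) else NULL
  grid <- expand.grid(mechanism = mechanisms, proportion = proportions,
                      method = methods, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid) * length(traits))
  k <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub_seed <- (seed * 1000L +
                 match(g$mechanism, c("MCAR", "MAR_AW", "MAR_HD")) * 101L +
                 round(g$proportion * 100) * 7L + g$rep) %% .Machine$integer.max
    holed <- inject_missingness(train_table, g$mechanism, g$proportion,
                                traits = traits, tree = tree, seed = sub_seed)
    imp <- switch(g$method,
      phylo = bm_impute(tree, holed, traits = c("AW", traits)),
      mean  = mean_impute(holed, traits = c("AW", traits)),
      pmm   = pmm_impute(holed, traits = c("AW", traits), covariates = covs))
    for (tr in traits) {
      k <- k + 1
      out[[k]] <- data.frame(
        mechanism = g$mechanism, proportion = g$proportion,
        method = g$method, rep = g$rep, trait = tr,
        nrmse = nrmse(imp, train_table, tr),
        slope_bias = slope_bias(train_table, imp, tr),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
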