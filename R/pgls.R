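# Per-gene phylogenetic regression.  Expression (species means) is regressed
# on a longevity trait under three residual models: OLS (iid), Brownian
# motion (covariance proportional to shared branch length) and stationary
# Ornstein-Uhlenbeck (covariance decaying with patristic distance, alpha
# profiled by maximum likelihood).  The best model is chosen by AIC (a raw
# maximum-likelihood switch reproduces a literal ML selection; note OU nests
# BM, so raw ML always weakly prefers OU).

# Core GLS fit via the Cholesky whitening transform.  Returns NULL when x is
# constant.  P values use a t test with n - 2 df; the log-likelihood is the
# Gaussian ML value (sigma^2 profiled).
.fit_core <- function(y, x, cho = NULL, logdet = 0) {
  n <- length(y)
  if (is.null(cho)) {
    t1 <- rep(1, n); tx <- x; ty <- y
  } else {
    tc <- t(cho)
    t1 <- forwardsolve(tc, rep(1, n))
    tx <- forwardsolve(tc, x)
    ty <- forwardsolve(tc, y)
  }
  Z <- cbind(t1, tx)
  fit <- stats::.lm.fit(Z, ty)
  if (fit$rank < 2) return(NULL)
  r <- fit$residuals
  rss <- sum(r^2)
  df <- n - 2
  XtXi <- chol2inv(chol(crossprod(Z)))
  degenerate <- rss < 1e-12 * max(sum(ty^2), 1)
  if (degenerate) {
    se <- 0; tstat <- Inf; p <- 1   # flat-fit convention: flagged, P = 1
  } else {
    se <- sqrt(rss / df * XtXi[2, 2])
    tstat <- fit$coefficients[2] / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  sig2_ml <- rss / n
  ll <- if (degenerate) Inf else
    -0.5 * (n * log(2 * pi) + n * log(sig2_ml) + n) - 0.5 * logdet
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       se = se, t = unname(tstat), p = unname(p), logLik = ll,
       sigma2 = sig2_ml, n = n, degenerate = degenerate)
}

.as_fit_result <- function(core, model, k_params, alpha = NA_real_) {
  if (is.null(core)) return(NULL)
  structure(c(core, list(model = model, k_params = k_params, alpha = alpha)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: slope %.4g (se %.3g), t %.3g, P %.3g, logLik %.4g, n %d%s\n",
              x$model, x$slope, x$se, x$t, x$p, x$logLik, x$n,
              if (is.finite(x$alpha)) sprintf(", alpha %.3g", x$alpha) else ""))
  invisible(x)
}

.align_xy <- function(y, x) {
  if (is.null(names(y)) || is.null(names(x)))
    stop("y and x must be named by species")
  common <- intersect(names(y)[!is.na(y)], names(x)[!is.na(x)])
  list(y = y[common], x = x[common], taxa = common)
}

#' Ordinary least-squares fit of expression on a trait
#'
#' @param y Named expression values (species means; `NA` = masked).
#' @param x Named trait values.
#' @return A `fit_result` (model `"OLS"`, 3 parameters) or an error for
#'   constant x.
#' @export
fit_ols <- function(y, x) {
  al <- .align_xy(y, x)
  if (length(al$y) < 4) stop("need >= 4 paired observations")
  if (stats::var(al$x) == 0) stop("zero variance in x")
  .as_fit_result(.fit_core(al$y, al$x), "OLS", 3)
}

#' Phylogenetic GLS under Brownian motion
#'
#' Generalized least squares with error covariance proportional to the BM
#' covariance of the tree pruned to the species observed for this gene.
#' On a star phylogeny this reduces exactly to [fit_ols()].
#'
#' @inheritParams fit_ols
#' @param tree `phylo` whose tips cover the observed species.
#' @return A `fit_result` (model `"BM"`, 3 parameters).
#' @export
fit_pgls_bm <- function(y, x, tree) {
  al <- .align_xy(y, x)
  if (length(al$y) < 4) stop("need >= 4 paired observations")
  C <- bm_covariance(tree, al$taxa)
  .fit_bm(al$y, al$x, C)
}

.fit_bm <- function(y, x, C) {
  cho <- tryCatch(chol(C), error = function(e) stop("singular BM covariance"))
  .as_fit_result(.fit_core(y, x, cho, 2 * sum(log(diag(cho)))), "BM", 3)
}

#' Phylogenetic GLS under a stationary Ornstein-Uhlenbeck model
#'
#' The OU covariance [ou_covariance()] recovers BM as alpha tends to the
#' lower bound and iid errors at the upper bound; alpha is estimated by
#' profile maximum likelihood over log-spaced bounds (coarse grid plus a
#' golden-section refinement).
#'
#' @inheritParams fit_pgls_bm
#' @param alpha_bounds `c(lo, hi)` on alpha (1/Myr); defaults to
#'   `c(1e-3, 100) / depth`.
#' @param grid_n Points in the coarse log-spaced grid.
#' @return A `fit_result` (model `"OU"`, 4 parameters including alpha).
#' @export
fit_pgls_ou <- function(y, x, tree, alpha_bounds = NULL, grid_n = 8) {
  al <- .align_xy(y, x)
  if (length(al$y) < 4) stop("need >= 4 paired observations")
  C <- bm_covariance(tree, al$taxa)
  d <- patristic_distances(prune_tree(tree, al$taxa))[al$taxa, al$taxa]
  .fit_ou(al$y, al$x, C, d, alpha_bounds, grid_n)
}

.fit_ou <- function(y, x, C, d, alpha_bounds = NULL, grid_n = 8) {
  depth <- max(diag(C))
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-3, 100) / depth
  ll_at <- function(a) {
    V <- ou_covariance(C, d, a)
    cho <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cho)) return(list(ll = -Inf))
    core <- .fit_core(y, x, cho, 2 * sum(log(diag(cho))))
    if (is.null(core)) return(list(ll = -Inf))
    list(ll = core$logLik, core = core)
  }
  grid <- exp(seq(log(alpha_bounds[1]), log(alpha_bounds[2]),
                  length.out = grid_n))
  lls <- vapply(grid, function(a) ll_at(a)$ll, numeric(1))
  if (all(!is.finite(lls))) stop("OU optimizer failed on all grid points")
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  # alpha only needs ~5% relative resolution; the likelihood is flat there
  opt <- stats::optimize(function(la) ll_at(exp(la))$ll, c(log(lo), log(hi)),
                         maximum = TRUE, tol = 0.05)
  a_hat <- exp(opt$maximum)
  if (opt$objective < lls[i]) a_hat <- grid[i]
  res <- ll_at(a_hat)
  .as_fit_result(res$core, "OU", 4, alpha = a_hat)
}

#' Select the best residual model for one gene
#'
#' @param fits List of `fit_result`s computed on identical observations.
#' @param criterion `"AIC"` (default) or `"ML"` (raw maximum likelihood,
#'   which weakly prefers OU because it nests BM).
#' @return The chosen `fit_result`.  Ties go to the simpler model in the
#'   order OLS, BM, OU.
#' @export
select_model <- function(fits, criterion = c("AIC", "ML")) {
  criterion <- match.arg(criterion)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all fits failed")
  pref <- c(OLS = 1, BM = 2, OU = 3)
  ord <- order(pref[vapply(fits, `[[`, "", "model")])
  fits <- fits[ord]
  score <- vapply(fits, function(f)
    if (criterion == "AIC") 2 * f$k_params - 2 * f$logLik else -f$logLik,
    numeric(1))
  fits[[which(score <= min(score) + 1e-9)[1]]]
}

# Fit the requested models on one gene's aligned data, given precomputed
# covariance blocks (C, d indexed by taxa).  Used by the robust procedure to
# avoid re-pruning the tree at every leave-one-out refit.
.fit_gene <- function(y, x, C, d, models, criterion = "AIC", grid_n = 6) {
  fits <- list()
  if ("OLS" %in% models && stats::var(x) > 0)
    fits$OLS <- .as_fit_result(.fit_core(y, x), "OLS", 3)
  if ("BM" %in% models)
    fits$BM <- tryCatch(.fit_bm(y, x, C), error = function(e) NULL)
  if ("OU" %in% models)
    fits$OU <- tryCatch(.fit_ou(y, x, C, d, grid_n = grid_n),
                        error = function(e) NULL)
  list(fits = fits, best = select_model(fits, criterion))
}
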