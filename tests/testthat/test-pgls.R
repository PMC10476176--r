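# Model fits, model selection, the two-step robust procedure and the maxT
# adjustment engine.

test_that("fit_ols matches the normal equations and is order-invariant", {
  x <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  y <- setNames(c(2.1, 3.9, 6.2, 8.1, 9.8), letters[1:5])
  f <- fit_ols(y, x)
  o <- gls_oracle(y, x, diag(5))
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$se, o$se, tolerance = 1e-10)
  expect_equal(f$p, o$p, tolerance = 1e-10)
  sh <- c(3, 5, 1, 4, 2)
  f2 <- fit_ols(y[sh], x[sh])
  expect_equal(f2$slope, f$slope, tolerance = 1e-12)
  # exact line -> degenerate flag, P = 1
  fd <- fit_ols(setNames(2 * x, names(x)), x)
  expect_true(fd$degenerate)
  expect_equal(fd$p, 1)
  expect_error(fit_ols(y, setNames(rep(1, 5), names(x))), "variance")
})

test_that("fit_pgls_bm matches the explicit GLS oracle on small trees", {
  for (n in c(4, 8)) {
    tr <- simulate_tree(n, seed = n)
    C <- bm_covariance(tr)
    set.seed(n + 1)
    y <- setNames(rnorm(n), rownames(C))
    x <- setNames(rnorm(n), rownames(C))
    f <- fit_pgls_bm(y, x, tr)
    o <- gls_oracle(y, x, C)
    expect_equal(f$slope, o$slope, tolerance = 1e-8)
    expect_equal(f$se, o$se, tolerance = 1e-8)
    expect_equal(f$p, o$p, tolerance = 1e-8)
    expect_equal(f$logLik, o$logLik, tolerance = 1e-8)
  }
})

test_that("star tree reduces BM (and large-alpha OU) to OLS", {
  st <- star_tree(12, len = 150)
  set.seed(2)
  y <- setNames(rnorm(12), st$tip.label)
  x <- setNames(rnorm(12), st$tip.label)
  fo <- fit_ols(y, x)
  fb <- fit_pgls_bm(y, x, st)
  expect_equal(fb$slope, fo$slope, tolerance = 1e-8)
  expect_equal(fb$se, fo$se, tolerance = 1e-8)
  expect_equal(fb$p, fo$p, tolerance = 1e-8)
})

test_that("OU nests BM (lower bound) and OLS (upper bound)", {
  tr <- simulate_tree(16, seed = 3)
  C <- bm_covariance(tr); d <- patristic_distances(tr)[rownames(C), rownames(C)]
  set.seed(4)
  L <- chol(C)
  y <- setNames(drop(crossprod(L, rnorm(16))) * 0.1, rownames(C))
  x <- setNames(rnorm(16), rownames(C))
  fb <- fit_pgls_bm(y, x, tr)
  depth <- max(diag(C))
  # OU log-likelihood evaluated at the alpha lower bound ~= BM value
  ou_lo <- gls_oracle(y, x, ou_covariance(C, d, 1e-5 / depth))
  expect_lt(abs(ou_lo$logLik - fb$logLik), 1e-3)
  # at the upper bound the covariance is effectively diagonal -> OLS
  fo <- fit_ols(y, x)
  ou_hi <- gls_oracle(y, x, ou_covariance(C, d, 100 / depth))
  expect_lt(abs(ou_hi$logLik - fo$logLik), 1e-3)
  ou_hi2 <- gls_oracle(y, x, ou_covariance(C, d, 1000 / depth))
  expect_equal(ou_hi2$slope, fo$slope, tolerance = 1e-8)
  expect_equal(ou_hi2$p, fo$p, tolerance = 1e-8)
  # profiled fit is at least as good as both endpoints
  fu <- fit_pgls_ou(y, x, tr)
  expect_gte(fu$logLik, fb$logLik - 1e-3)
  expect_true(fu$alpha >= 1e-3 / depth && fu$alpha <= 100 / depth)
})

test_that("OU recovers its own alpha within a factor of 2 (median)", {
  tr <- simulate_tree(96, seed = 5)
  C <- bm_covariance(tr); d <- patristic_distances(tr)[rownames(C), rownames(C)]
  alpha_true <- 0.05
  V <- ou_covariance(C, d, alpha_true)
  L <- chol(V)
  set.seed(6)
  x <- setNames(rnorm(96), rownames(C))
  a_hat <- replicate(20, {
    y <- setNames(drop(crossprod(L, rnorm(96))), rownames(C))
    fit_pgls_ou(y, x, tr)$alpha
  })
  expect_gt(median(a_hat), alpha_true / 2)
  expect_lt(median(a_hat), alpha_true * 2)
})

test_that("select_model prefers the generating model and breaks ties simply", {
  tr <- simulate_tree(48, seed = 7)
  C <- bm_covariance(tr)
  sp <- rownames(C)
  set.seed(8)
  x <- setNames(rnorm(48), sp)
  n_rep <- 60
  pick <- function(gen) {
    replicate(n_rep, {
      y <- if (gen == "iid") setNames(rnorm(48), sp) else
        setNames(drop(crossprod(chol(C / max(diag(C))), rnorm(48))), sp)
      select_model(list(fit_ols(y, x), fit_pgls_bm(y, x, tr),
                        fit_pgls_ou(y, x, tr)))$model
    })
  }
  expect_gt(mean(pick("iid") == "OLS"), 0.5)
  expect_gt(mean(pick("BM") %in% c("BM", "OU")), 0.5)
  # exact tie -> simpler model wins in the order OLS < BM < OU
  f1 <- structure(list(model = "OU", logLik = 0, k_params = 3),
                  class = "fit_result")
  f2 <- structure(list(model = "OLS", logLik = 0, k_params = 3),
                  class = "fit_result")
  expect_equal(select_model(list(f1, f2))$model, "OLS")
})

test_that("robust_pvalues defuses a constructed outlier and keeps signal", {
  st <- star_tree(24, len = 150)
  set.seed(1)
  x <- setNames(c(rnorm(23), 5), st$tip.label)
  y <- setNames(c(rnorm(23, 0, 0.1), 2), st$tip.label)
  rp <- robust_pvalues(y, x, st, models = "OLS")
  expect_lt(rp$p_raw, 0.01)
  expect_gt(rp$p_robust, 0.05)
  expect_equal(rp$dropped, "s24")   # the constructed species is the one cut
  # strong uniform association survives every leave-one-out
  p <- sim_panel(64, seed = 5)
  set.seed(43)
  yy <- 2 + 0.6 * p$trait + rnorm(64, 0, 0.3)
  names(yy) <- names(p$trait)
  rp2 <- robust_pvalues(yy, p$trait, p$tree)
  expect_lt(rp2$p_max, 0.05)
  expect_gte(rp2$p_max, max(rp2$loo_p) - 1e-15)
  # floor: n = 5 with floor 6 -> skip record, no crash
  short <- robust_pvalues(yy[1:5], p$trait, p$tree)
  expect_true(short$skipped)
  expect_match(short$reason, "floor")
})

test_that("robust_pvalues ignores masked species and species order", {
  p <- sim_panel(20, seed = 9)
  set.seed(10)
  y <- 1 + 0.4 * p$trait + rnorm(20, 0, 0.4)
  names(y) <- names(p$trait)
  rp <- robust_pvalues(y, p$trait, p$tree)
  sh <- sample(20)
  rp_sh <- robust_pvalues(y[sh], p$trait[sh], p$tree)
  expect_equal(rp_sh$p_robust, rp$p_robust, tolerance = 1e-10)
  expect_equal(rp_sh$p_max, rp$p_max, tolerance = 1e-10)
  y_ext <- c(y, extra1 = NA, extra2 = NA)
  x_ext <- c(p$trait, extra1 = 1, extra2 = 2)
  rp_ext <- robust_pvalues(y_ext, x_ext, p$tree)
  expect_equal(rp_ext$p_robust, rp$p_robust, tolerance = 1e-12)
})

test_that("the permutation engine reproduces a direct slow computation", {
  p <- sim_panel(16, seed = 12)
  set.seed(13)
  y <- setNames(rnorm(16), names(p$trait))
  expr <- matrix(y, 1, dimnames = list("g1", names(p$trait)))
  C <- bm_covariance(p$tree)[names(p$trait), names(p$trait)]
  adj <- adjust_pvalues(expr, p$trait, p$tree, gene_models = c(g1 = "BM"),
                        n_perm = 199, seed = 14)
  slow_gls_t <- function(yy, xx, CC) {
    o <- gls_oracle(yy, xx, CC)
    list(t = o$t, coef = c(o$intercept, o$slope))
  }
  f0 <- slow_gls_t(y, p$trait, C)
  res <- y - f0$coef[1] - f0$coef[2] * p$trait
  s <- names(which.max(abs(res)))
  s1 <- setdiff(names(y), s)
  t_rob <- abs(slow_gls_t(y[s1], p$trait[s1], C[s1, s1])$t)
  loo <- vapply(s1, function(t2) {
    k <- setdiff(s1, t2)
    abs(slow_gls_t(y[k], p$trait[k], C[k, k])$t)
  }, numeric(1))
  expect_equal(adj$t_robust, t_rob, tolerance = 1e-8)
  expect_equal(adj$t_min, min(loo), tolerance = 1e-8)
  # single gene: adjusted equals that gene's permutation P
  expect_equal(adj$p_robust_adj, adj$p_robust_perm)
  expect_equal(adj$p_max_adj, adj$p_max_perm)
})

test_that("maxT adjusted P values dominate per-gene permutation P values", {
  p <- sim_panel(24, seed = 15)
  sim <- simulate_expression(p$tree, p$trait, n_genes = 15,
                             frac_associated = 0.2, residual_model = "BM",
                             n_replicates = 1, rep_sd = 0, seed = 16)
  expr <- species_mean(sim$expr, "liver")
  adj <- suppressWarnings(
    adjust_pvalues(expr, p$trait, p$tree, n_perm = 99, seed = 17))
  expect_true(all(adj$p_robust_adj >= adj$p_robust_perm - 1e-12))
  expect_true(all(adj$p_max_adj >= adj$p_max_perm - 1e-12))
  expect_true(all(adj$p_robust_adj > 0 & adj$p_robust_adj <= 1))
  # deterministic under the seed
  adj2 <- suppressWarnings(
    adjust_pvalues(expr, p$trait, p$tree, n_perm = 99, seed = 17))
  expect_identical(adj, adj2)
})

test_that("call_longevity_genes applies strict cutoffs and the >=2 rule", {
  rec <- data.frame(
    gene = c("g1", "g1", "g2", "g3", "g3"),
    tissue = "liver",
    trait = c("ML", "FTM", "MLres", "ML", "FTM"),
    slope = c(0.5, 0.4, -0.2, 0.3, -0.3),
    p_robust_adj = c(0.001, 0.004, 0.002, 0.005, 0.001),
    p_max_adj = c(0.01, 0.04, 0.01, 0.01, 0.02))
  calls <- call_longevity_genes(rec)
  expect_true(calls$longevity_correlated[calls$gene == "g1"])
  expect_equal(calls$direction[calls$gene == "g1"], "positive")
  # one significant trait only -> not longevity-correlated
  expect_false(calls$longevity_correlated[calls$gene == "g2"])
  # P_robust.adj exactly 0.005 fails the strict inequality
  expect_equal(calls$n_sig_traits[calls$gene == "g3"], 1)
})
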