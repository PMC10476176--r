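# Shared fixtures and independent oracles, all built in code.

# Small fixed tree used across core tests: ((A:1,B:1):1,C:2);
abc_tree <- function() {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  attr(tr, "ultrametric") <- TRUE
  tr
}

star_tree <- function(n = 10, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr
}

# Independent GLS oracle: explicit (X' V^-1 X)^-1 X' V^-1 y matrix algebra,
# with the same df = n - 2 t test as the implementation under test.
gls_oracle <- function(y, x, V) {
  n <- length(y)
  X <- cbind(1, x)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
  covb <- sigma2 * solve(XtVi %*% X)
  tstat <- beta[2] / sqrt(covb[2, 2])
  list(intercept = beta[1], slope = beta[2], se = sqrt(covb[2, 2]),
       t = tstat, p = 2 * pt(-abs(tstat), n - 2),
       logLik = {
         s2 <- drop(t(r) %*% Vi %*% r) / n
         -0.5 * (n * log(2 * pi) + n * log(s2) + n) -
           0.5 * determinant(V)$modulus[1]
       })
}

# Independent TMM oracle: explicit loops over the trimmed-mean formula.
tmm_oracle <- function(counts, ref_col, logratio_trim = 0.30, sum_trim = 0.05) {
  lib <- colSums(counts)
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    obs <- counts[, j]; ref <- counts[, ref_col]
    ok <- obs > 0 & ref > 0
    M <- log2((obs[ok] / lib[j]) / (ref[ok] / lib[ref_col]))
    A <- 0.5 * log2((obs[ok] / lib[j]) * (ref[ok] / lib[ref_col]))
    w <- (lib[j] - obs[ok]) / (lib[j] * obs[ok]) +
      (lib[ref_col] - ref[ok]) / (lib[ref_col] * ref[ok])
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
    keep <- rep(FALSE, n)
    rM <- rank(M); rA <- rank(A)
    for (i in seq_len(n))
      keep[i] <- rM[i] >= loM && rM[i] <= hiM && rA[i] >= loA && rA[i] <= hiA
    f[j] <- 2^(sum((1 / w[keep]) * M[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Build an expr_matrix of counts directly from a plain matrix (one sample
# per species by default).
counts_em <- function(mat, species = colnames(mat), tissue = "liver") {
  samples <- data.frame(sample_id = colnames(mat), species = species,
                        tissue = tissue, replicate = 1L, batch = "b1",
                        stringsAsFactors = FALSE)
  expression_matrix(mat, samples, scale_tag = "counts")
}

rand_counts <- function(n_genes, n_samples, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Simulated trait panel reused by pgls tests.
sim_panel <- function(n_tips = 32, seed = 11) {
  tr <- simulate_tree(n_tips, seed = seed)
  lh <- simulate_life_history(tr, seed = seed + 1)
  trait <- setNames(log2(lh$table$ML), lh$table$species)
  list(tree = tr, life = lh$table, trait = trait)
}

# Brute-force 1-D PAM oracle: scan every medoid pair.
pam_bruteforce <- function(x) {
  n <- length(x)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(abs(x - x[i]), abs(x - x[j])))
    if (is.null(best) || cost < best$cost)
      best <- list(cost = cost, medoids = sort(c(x[i], x[j])))
  }
  best
}

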