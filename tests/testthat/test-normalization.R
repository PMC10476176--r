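# Filters, TMM, RPKM, Tau and PCA.

test_that("low-expression filter applies the <10-in->=4-samples rule", {
  m <- rand_counts(3, 6, seed = 2, lambda = 50)
  m[1, 1:4] <- 5        # low in exactly 4 samples -> removed
  m[2, 1:3] <- 5        # low in exactly 3 samples -> retained
  out <- filter_low_expression(counts_em(m))
  expect_equal(rownames(out$values), c("g002", "g003"))
  expect_equal(attr(out, "removed"), "g001")
  # masked cells count as neither pass nor fail
  m2 <- m; m2[2, 4:6] <- NA
  out2 <- filter_low_expression(counts_em(m2))
  expect_true("g002" %in% rownames(out2$values))
  # all pass -> unchanged
  all_hi <- rand_counts(4, 6, seed = 3, lambda = 100)
  expect_equal(nrow(filter_low_expression(counts_em(all_hi))$values), 4)
})

test_that("dominant-gene filter removes genes at >= 5% of the total", {
  m <- matrix(10, 100, 4, dimnames = list(sprintf("g%03d", 1:100),
                                          sprintf("s%02d", 1:4)))
  m[1, ] <- 260   # 1040 of 5000 = 6.2% adjusted below
  tot_others <- sum(m[-1, ])
  m[1, ] <- round(0.06 * tot_others / (4 * (1 - 0.06)))  # ~6% share
  out <- filter_dominant_gene(counts_em(m))
  expect_false("g001" %in% rownames(out$values))
  m[1, ] <- round(0.04 * tot_others / (4 * (1 - 0.04)))  # ~4% share
  expect_true("g001" %in% rownames(filter_dominant_gene(counts_em(m))$values))
  one <- m[1, , drop = FALSE]
  expect_equal(nrow(filter_dominant_gene(counts_em(one))$values), 0)
})

test_that("min-species filter uses the presence mask with a strict boundary", {
  m <- rand_counts(3, 10, seed = 4)
  m[1, 1:3] <- NA   # g001 present in 7 of 10 species
  em <- counts_em(m)
  expect_false("g001" %in% rownames(filter_min_species(em, 8)$values))
  expect_true("g001" %in% rownames(filter_min_species(em, 7)$values))
  expect_equal(nrow(filter_min_species(em, 1)$values), 3)
})

test_that("tmm_factors match the independent oracle and edgeR", {
  m <- rand_counts(200, 4, seed = 5, lambda = 40)
  m[, 2] <- rpois(200, 120)   # composition + depth differences
  em <- counts_em(m)
  f <- tmm_factors(em)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  # reference column chosen as in the implementation, oracle coded with
  # explicit loops in the helper
  lib <- colSums(m)
  f75 <- vapply(1:4, function(j) quantile(m[, j] / lib[j], 0.75, names = FALSE),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  expect_equal(unname(f), tmm_oracle(m, ref), tolerance = 1e-6)
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f), unname(fe), tolerance = 1e-6)
})

test_that("TMM is exact for identical and purely depth-shifted libraries", {
  m <- rand_counts(150, 2, seed = 6)
  m[, 2] <- m[, 1]
  expect_equal(unname(tmm_factors(counts_em(m))), c(1, 1), tolerance = 1e-12)
  m[, 2] <- 3 * m[, 1]
  em <- counts_em(m)
  lens <- setNames(rep(1000, 150), rownames(m))
  norm <- log2_tmm_rpkm(em, lens)
  expect_equal(norm$values[, 1], norm$values[, 2], tolerance = 1e-10)
  # sample-relabeling invariance
  m2 <- m[, 2:1]
  expect_equal(unname(tmm_factors(counts_em(m2))),
               unname(rev(tmm_factors(em))), tolerance = 1e-12)
})

test_that("log2 TMM-RPKM matches the closed form", {
  m <- matrix(c(10, 10), 1, 2, dimnames = list("g1", c("s1", "s2")))
  em <- counts_em(m)
  # force effective library 1e6 via explicit unit factors on lib = 20?  use
  # direct closed form instead: count 10, len 1000 bp, lib 1e6 -> RPKM 10
  lens <- c(g1 = 1000)
  big <- rand_counts(2, 2, seed = 7)
  big[1, ] <- 10
  big[2, ] <- 1e6 - 10  # library exactly 1e6
  em2 <- counts_em(big)
  norm <- log2_tmm_rpkm(em2, c(g001 = 1000, g002 = 1000),
                        factors = c(s01 = 1, s02 = 1))
  expect_equal(unname(norm$values[1, 1]), log2(10 + 1))
  # zero count -> log2(1) = 0
  big[1, 1] <- 0
  norm0 <- log2_tmm_rpkm(counts_em(big), c(g001 = 1000, g002 = 1000),
                         factors = c(s01 = 1, s02 = 1))
  expect_equal(unname(norm0$values[1, 1]), 0)
  # factor 2 halves RPKM
  norm2 <- log2_tmm_rpkm(em2, c(g001 = 1000, g002 = 1000),
                         factors = c(s01 = 2, s02 = 1))
  expect_equal(2^norm2$values[1, 1] - 1, (2^norm$values[1, 1] - 1) / 2,
               tolerance = 1e-10)
  expect_error(log2_tmm_rpkm(em2, c(g001 = 1000)), "g002")
})

test_that("species_mean averages replicates and propagates masks", {
  vals <- matrix(c(1, 3, 5, NA, NA, NA), 1, 6)
  dimnames(vals) <- list("g1", sprintf("s%d", 1:6))
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        species = rep(c("A", "B", "C"), each = 2),
                        tissue = "liver", replicate = rep(1:2, 3),
                        batch = "b")
  em <- expression_matrix(vals, samples, scale_tag = "log2_tmm_rpkm")
  sm <- species_mean(em, "liver")
  expect_equal(sm["g1", "A"], 2)      # mean of (1, 3)
  expect_equal(sm["g1", "B"], 5)      # single observed replicate
  expect_true(is.na(sm["g1", "C"]))   # all replicates masked
  expect_error(species_mean(em, "brain"), "tissue")
})

test_that("tau_index follows the formula, thresholds and invariances", {
  expect_equal(tau_index(c(7, 7, 7, 7))$tau, 0)
  expect_equal(tau_index(c(9, 0, 0, 0, 0))$tau, 1)
  r <- tau_index(c(1.0, 0.5, 0.0))
  expect_equal(r$tau, 0.75)
  expect_equal(r$class, "intermediate")
  # scale invariance
  expect_equal(tau_index(c(4, 2, 0) * 13)$tau, 0.75)
  # masked species excluded from N
  expect_equal(tau_index(c(1.0, 0.5, 0.0, NA))$n_species, 3)
  # monotone under concentration: nested vectors with mass moved into one
  # species never decrease tau
  v <- c(10, 8, 6, 4, 2)
  taus <- sapply(0:4, function(k) {
    w <- v; w[seq_len(k) + 1] <- 0; tau_index(w)$tau
  })
  expect_true(all(diff(taus) >= -1e-12))
  # all-zero -> flagged undefined, not 0
  z <- tau_index(c(0, 0, 0))
  expect_false(z$defined)
  expect_true(is.na(z$tau))
  expect_error(tau_index(c(1)), ">= 2")
  # table form agrees with the scalar form
  m <- rbind(g1 = c(1, 0.5, 0), g2 = c(3, 3, 3))
  colnames(m) <- c("A", "B", "C")
  tt <- tau_table(m)
  expect_equal(tt$tau, c(0.75, 0))
  expect_equal(tt$class, c("intermediate", "broad"))
})

test_that("pca_top_variance ranks by variance and yields sane fractions", {
  set.seed(8)
  m <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:12)))
  m[1:5, ] <- m[1:5, ] * 10
  res <- pca_top_variance(m, n_top = 5000)  # fewer genes than n_top -> all
  expect_length(res$genes, 100)
  res2 <- pca_top_variance(m, n_top = 10)
  v <- apply(m, 1, var)
  expect_setequal(res2$genes, names(sort(v, decreasing = TRUE))[1:10])
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-8)
  expect_error(pca_top_variance(m[, 1, drop = FALSE]), "2")
})
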