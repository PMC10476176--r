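# Directional scores, RescaleBins, SUMSTAT nulls and Fisher categories.

test_that("directional_scores implement both zeroing rules", {
  co <- c(g1 = 2, g2 = -1, g3 = 0)
  expect_equal(unname(directional_scores(co, "positive")), c(2, 0, 0))
  expect_equal(unname(directional_scores(co, "negative")), c(0, 1, 0))
  z <- c(a = 0, b = 0)
  expect_equal(directional_scores(z, "positive"), z)
})

test_that("rescale_bins standardizes within covariate bins", {
  set.seed(1)
  n <- 200
  cov <- runif(n, 100, 5000)
  sc <- setNames(0.001 * cov + rnorm(n), sprintf("g%03d", 1:n))
  out <- rescale_bins(sc, cov, n_bins = 5)
  bins <- attr(out, "bins")
  for (b in unique(bins)) {
    expect_equal(mean(out[bins == b]), 0, tolerance = 1e-12)
    expect_equal(sd(out[bins == b]), 1, tolerance = 1e-12)
  }
  # n_bins = 1 -> global standardization
  g <- rescale_bins(sc, cov, n_bins = 1)
  expect_equal(as.vector(g), unname(scale(sc)[, 1]), tolerance = 1e-12)
  # already standardized within bins -> unchanged
  again <- rescale_bins(out, cov, n_bins = 5)
  expect_equal(as.vector(again), as.vector(out), tolerance = 1e-12)
})

test_that("set_sumstat sums members and is additive over disjoint sets", {
  sc <- c(g1 = 1, g2 = 2, g3 = 3)
  expect_equal(set_sumstat(c("g1", "g3"), sc), 4)
  expect_equal(set_sumstat("g2", sc), 2)
  A <- "g1"; B <- c("g2", "g3")
  expect_equal(set_sumstat(c(A, B), sc),
               set_sumstat(A, sc) + set_sumstat(B, sc))
  expect_warning(set_sumstat(c("g1", "nope"), sc), "not in")
  expect_error(set_sumstat("nope", sc), "score")
})

test_that("empirical set P matches exhaustive enumeration on 8 genes", {
  set.seed(2)
  sc <- setNames(round(rnorm(8), 2), sprintf("g%d", 1:8))
  combos <- combn(8, 3)
  all_sums <- apply(combos, 2, function(i) sum(sc[i]))
  target <- c("g1", "g4", "g7")
  obs <- sum(sc[target])
  p_exact <- mean(all_sums >= obs)
  n_draws <- 20000
  r <- empirical_set_pvalue(target, sc, n_draws = n_draws, seed = 3,
                            mode = "empirical")
  se <- sqrt(p_exact * (1 - p_exact) / n_draws)
  expect_lt(abs(r$p - p_exact), 3 * se + 2 / n_draws)
  expect_equal(r$null_method, "empirical")
  # gene-order exchangeability
  r2 <- empirical_set_pvalue(target, sc[sample(8)], n_draws = n_draws,
                             seed = 3, mode = "empirical")
  expect_lt(abs(r2$p - p_exact), 3 * se + 2 / n_draws)
})

test_that("empirical P handles ties, floors and the normal branch", {
  # all genes share one score: every null set ties -> P = 1
  sc <- setNames(rep(2, 10), sprintf("g%d", 1:10))
  r <- empirical_set_pvalue(c("g1", "g2"), sc, n_draws = 500, seed = 4,
                            mode = "empirical")
  expect_equal(r$p, 1)
  # a set beating every draw still gets P = 1/(draws+1), never 0
  sc2 <- setNames(c(100, 99, 98, rep(0, 197)), sprintf("g%d", 1:200))
  r2 <- empirical_set_pvalue(c("g1", "g2", "g3"), sc2, n_draws = 999,
                             seed = 5, mode = "empirical")
  expect_equal(r2$p, 1 / 1000)
  # normal branch agrees with the empirical branch for Gaussian scores
  set.seed(6)
  sc3 <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  st <- names(sort(sc3, decreasing = TRUE))[c(3, 17, 40, 90, 200, 330)]
  pn <- empirical_set_pvalue(st, sc3, mode = "normal")$p
  pe <- empirical_set_pvalue(st, sc3, n_draws = 50000, seed = 7,
                             mode = "empirical")$p
  expect_lt(abs(pn - pe) / pe, 0.10)
  expect_error(empirical_set_pvalue(sprintf("g%03d", 1:500), sc3), "universe")
})

test_that("empirical set P values are uniform under a random-score null", {
  set.seed(8)
  sc <- setNames(runif(60), sprintf("g%02d", 1:60))
  ps <- vapply(1:400, function(i) {
    st <- sample(names(sc), 5)
    empirical_set_pvalue(st, sc, n_draws = 400, seed = 100 + i,
                         mode = "empirical")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("fisher_category_enrichment matches the hypergeometric closed form", {
  uni <- sprintf("g%d", 1:8)
  hits <- uni[1:4]
  category <- uni[c(1, 2, 3, 5)]  # table (3,1,1,3)
  r <- fisher_category_enrichment(hits, category, uni, "greater")
  expect_equal(r$odds_ratio, 9)
  expect_equal(r$p, 17 / 70, tolerance = 1e-12)
  # category == universe -> OR flagged, P = 1
  r2 <- fisher_category_enrichment(hits, uni, uni)
  expect_true(is.na(r2$odds_ratio))
  expect_equal(r2$p, 1)
  # zero hits in category with positive expectation -> OR 0
  r3 <- fisher_category_enrichment(uni[5:8], uni[1:3], uni, "greater")
  expect_equal(r3$odds_ratio, 0)
  expect_error(fisher_category_enrichment(hits, category, character(0)),
               "empty")
})

test_that("build_categories applies the documented thresholds", {
  ann <- data.frame(gene = sprintf("g%02d", 1:20),
                    pli = c(0.95, 0.90, 0.89, runif(17, 0, 0.5)),
                    hi = seq(0, 1, length.out = 20),
                    age_class = rep(c("young", "old"), 10),
                    disease = c(TRUE, rep(FALSE, 19)),
                    cancer = c(FALSE, TRUE, rep(FALSE, 18)))
  cats <- build_categories(ann)
  expect_true("g01" %in% cats$essential)
  expect_false("g02" %in% cats$essential)   # pLI exactly 0.9: strict >
  expect_false("g03" %in% cats$essential)
  qs <- quantile(ann$hi, c(0.25, 0.75))
  expect_setequal(cats$haplo_insufficient, ann$gene[ann$hi > qs[2]])
  expect_setequal(cats$haplo_sufficient, ann$gene[ann$hi < qs[1]])
  med_gene <- ann$gene[which.min(abs(ann$hi - median(ann$hi)))]
  expect_false(med_gene %in% c(cats$haplo_insufficient, cats$haplo_sufficient))
  expect_equal(cats$disease, "g01")
  expect_equal(cats$cancer, "g02")
})

test_that("GMT round-trips", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back, sets)
  writeLines("badline", f)
  expect_error(read_gmt(f), "malformed")
})
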