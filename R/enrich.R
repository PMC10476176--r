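# Polygenic SUMSTAT gene-set enrichment.  A set's score is the sum of its
# members' gene scores; significance comes from a normal approximation when
# the scores pass a normality check, otherwise from random same-size sets
# drawn from the scored universe (default 400,000 draws at full scale).

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene ids.
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write gene sets to GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (defaults to set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Directional gene scores from signed regression coefficients
#'
#' Positive mode keeps positive coefficients and zeroes negatives; negative
#' mode zeroes positives and takes absolute values of negatives.  Either
#' way the resulting scores are non-negative and one-sided enrichment is
#' meaningful.
#'
#' @param coefficients Named signed coefficients (e.g. PGLS slopes).
#' @param direction `"positive"` or `"negative"`.
#' @return Named non-negative score vector.
#' @export
directional_scores <- function(coefficients, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  s <- coefficients
  if (direction == "positive") s[s < 0] <- 0 else { s[s > 0] <- 0; s <- abs(s) }
  s
}

#' Within-bin standardization of gene scores (RescaleBins)
#'
#' Gene scores correlate with covariates such as gene length or the number
#' of species a gene is measured in; binning by covariate quantiles and
#' standardizing within bins removes that confounding before SUMSTAT.
#' Bins with fewer than 2 genes are merged into their lower neighbor.
#'
#' @param scores Named numeric scores.
#' @param covariate Covariate, same genes.
#' @param n_bins Number of quantile bins (default 10).
#' @return Named rescaled scores with attribute `"bins"`.
#' @export
rescale_bins <- function(scores, covariate, n_bins = 10) {
  if (length(scores) != length(covariate)) stop("length mismatch")
  if (anyNA(covariate)) stop("covariate must be observed for all genes")
  if (n_bins < 1) stop("n_bins must be >= 1")
  br <- unique(stats::quantile(covariate, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(br) <= 2) rep(1L, length(scores)) else
    as.integer(cut(covariate, br, include.lowest = TRUE))
  # merge undersized bins downward
  repeat {
    tb <- table(bins)
    small <- as.integer(names(tb)[tb < 2])
    if (length(small) == 0 || length(tb) == 1) break
    s <- small[1]
    target <- if (s > min(bins)) max(bins[bins < s]) else min(bins[bins > s])
    bins[bins == s] <- target
  }
  out <- scores
  for (b in unique(bins)) {
    i <- bins == b
    mu <- mean(scores[i]); sd <- stats::sd(scores[i])
    out[i] <- if (is.na(sd) || sd == 0) 0 else (scores[i] - mu) / sd
  }
  attr(out, "bins") <- bins
  out
}

#' Sum statistic of a gene set
#'
#' @param set_members Character vector of member genes.
#' @param scores Named scores (universe).
#' @return Sum of member scores; members missing from the universe are
#'   dropped with a warning.
#' @export
set_sumstat <- function(set_members, scores) {
  hit <- set_members %in% names(scores)
  if (!any(hit)) stop("no set member has a score")
  if (!all(hit)) warning(sum(!hit), " set member(s) not in the scored universe")
  sum(scores[set_members[hit]])
}

#' Empirical (or normal-approximation) P value for a set's SUMSTAT
#'
#' In `auto` mode a Kolmogorov-Smirnov check decides whether the score
#' distribution is compatible with normal; if so, the P value comes from
#' the exact finite-population mean and variance of a size-m sum drawn
#' without replacement; otherwise from `n_draws` random same-size sets.
#' The empirical P is `(1 + #{null >= observed}) / (n_draws + 1)`, so it is
#' never 0 and ties count against significance.
#'
#' @param set Character vector of member genes.
#' @param scores Named scores (the universe null sets are drawn from).
#' @param n_draws Null draws (default 400000; scale down for tests).
#' @param seed Integer seed.
#' @param mode `"auto"`, `"normal"` or `"empirical"`.
#' @param alternative `"greater"` (default; directional scores encode sign)
#'   or `"two.sided"`.
#' @return data.frame row: `set_size`, `sumstat`, `p`, `null_method`,
#'   `n_draws`.
#' @export
empirical_set_pvalue <- function(set, scores, n_draws = 400000, seed = 1L,
                                 mode = c("auto", "normal", "empirical"),
                                 alternative = c("greater", "two.sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  N <- length(scores)
  if (length(unique(set)) > N) stop("set larger than the universe")
  set <- intersect(set, names(scores))
  m <- length(set)
  if (m == 0) stop("empty intersection with the scored universe")
  obs <- sum(scores[set])
  if (mode == "auto") {
    sd0 <- stats::sd(scores)
    ks_p <- if (sd0 == 0) 0 else
      suppressWarnings(stats::ks.test((scores - mean(scores)) / sd0, "pnorm")$p.value)
    mode <- if (ks_p > 0.05) "normal" else "empirical"
  }
  if (mode == "normal" && m < N) {
    mu <- mean(scores) * m
    pop_var <- mean((scores - mean(scores))^2)
    va <- m * pop_var * (N - m) / (N - 1)
    if (va == 0) { p <- 1 } else {
      z <- (obs - mu) / sqrt(va)
      p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
      else 2 * stats::pnorm(-abs(z))
    }
    return(data.frame(set_size = m, sumstat = obs, p = p,
                      null_method = "normal", n_draws = 0L))
  }
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i)
    sum(scores[sample.int(N, m)]), numeric(1))
  p <- if (alternative == "greater")
    (1 + sum(null >= obs)) / (n_draws + 1)
  else (1 + sum(abs(null - mean(null)) >= abs(obs - mean(null)))) / (n_draws + 1)
  data.frame(set_size = m, sumstat = obs, p = p,
             null_method = "empirical", n_draws = as.integer(n_draws))
}

#' SUMSTAT enrichment over a gene-set collection
#'
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param scores Named gene scores.
#' @param n_draws,seed,mode,alternative Passed to
#'   [empirical_set_pvalue()].
#' @return data.frame with one row per set, plus a BH column for
#'   convenience (raw P values are the primary output).
#' @export
sumstat_enrichment <- function(sets, scores, n_draws = 400000, seed = 1L,
                               mode = "auto", alternative = "greater") {
  rows <- lapply(seq_along(sets), function(i)
    cbind(data.frame(set = names(sets)[i], stringsAsFactors = FALSE),
          empirical_set_pvalue(sets[[i]], scores, n_draws = n_draws,
                               seed = seed + i, mode = mode,
                               alternative = alternative)))
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}

#' Fisher's exact category enrichment
#'
#' 2x2 table of hit/non-hit x in/out of category over the universe;
#' reports the sample odds ratio and the exact hypergeometric P.
#'
#' @param hits Gene list of interest (e.g. Up, Down, or Both).
#' @param category Category members.
#' @param universe All genes considered.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return data.frame row: counts, `odds_ratio`, `p`.
#' @export
fisher_category_enrichment <- function(hits, category, universe,
                                       alternative = c("greater", "less",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe")
  hits <- intersect(hits, universe)
  category <- intersect(category, universe)
  a <- length(intersect(hits, category))
  b <- length(hits) - a
  cc <- length(category) - a
  dd <- length(universe) - a - b - cc
  or <- if (b * cc == 0) {
    if (a * dd == 0) NA_real_ else Inf
  } else (a * dd) / (b * cc)
  if (cc + dd == 0 || a + b == 0) {
    p <- 1; or <- NA_real_   # category (or hits) spans the whole universe
  } else {
    p <- stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                            alternative = alternative)$p.value
  }
  data.frame(in_cat_hit = a, out_cat_hit = b, in_cat_other = cc,
             out_cat_other = dd, odds_ratio = or, p = p,
             alternative = alternative, stringsAsFactors = FALSE)
}

#' Build boolean gene categories from annotation tables
#'
#' Categories: `essential` (pLI > 0.9, strict), `haplo_insufficient` (top
#' quartile of the HI score after descending sort), `haplo_sufficient`
#' (bottom quartile), `young`/`old` (gene-age class), `disease`, `cancer`.
#'
#' @param annotations data.frame with `gene` plus any of `pli`, `hi`,
#'   `age_class` (`"young"`/`"old"`), `disease` (logical), `cancer`
#'   (logical).
#' @return Named list of character vectors.
#' @export
build_categories <- function(annotations) {
  if (is.null(annotations$gene)) stop("annotations need a gene column")
  g <- annotations$gene
  out <- list()
  if (!is.null(annotations$pli))
    out$essential <- g[!is.na(annotations$pli) & annotations$pli > 0.9]
  if (!is.null(annotations$hi)) {
    hi <- annotations$hi
    qs <- stats::quantile(hi, c(0.25, 0.75), na.rm = TRUE)
    out$haplo_insufficient <- g[!is.na(hi) & hi > qs[2]]
    out$haplo_sufficient <- g[!is.na(hi) & hi < qs[1]]
  }
  if (!is.null(annotations$age_class)) {
    out$young <- g[annotations$age_class %in% "young"]
    out$old <- g[annotations$age_class %in% "old"]
  }
  if (!is.null(annotations$disease)) out$disease <- g[isTRUE_vec(annotations$disease)]
  if (!is.null(annotations$cancer)) out$cancer <- g[isTRUE_vec(annotations$cancer)]
  if (length(out) == 0) stop("no recognized score columns in annotations")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
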