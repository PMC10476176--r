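# Integration with externally computed selection-intensity tables.  The
# relaxation parameter k relates foreground to background selection
# (omega_background^k = omega_foreground): k > 1 is intensified selection on
# the foreground (long-lived) branches, k < 1 relaxed.  The codon-model test
# itself is an input; this module interprets its per-gene k values.

#' Read a selection table (gene, k, p, omega1, omega2, omega3) from TSV
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_selection_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_selection_table(tab)
}

validate_selection_table <- function(tab) {
  need <- c("gene", "k")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("selection table lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene)) stop("duplicate genes in selection table")
  if (any(!is.na(tab$k) & tab$k <= 0)) stop("k must be > 0")
  tab
}

#' Exact 1-D partitioning around medoids (k = 2)
#'
#' Splits a numeric vector into two clusters minimizing the total absolute
#' deviation from the cluster medoids.  In one dimension the optimal
#' 2-medoid clustering is a split of the sorted values, so an exact scan
#' over split points (medoid = lower median of each side) is both exact and
#' deterministic; a brute-force scan over all medoid pairs gives the same
#' answer.
#'
#' @param lifespans Numeric vector (e.g. maximum lifespans in years).
#' @param k_clusters Currently only 2.
#' @return `list(labels, medoids, boundary, cost, degenerate)`; `labels`
#'   is 1 for the low cluster, 2 for the high; `boundary` is the midpoint
#'   between the adjacent extremes of the two clusters.
#' @export
pam_partition <- function(lifespans, k_clusters = 2) {
  if (k_clusters != 2) stop("only k_clusters = 2 is implemented")
  x <- lifespans[!is.na(lifespans)]
  if (length(x) < 2 * k_clusters) stop("need at least 2 values per cluster")
  if (length(unique(x)) == 1)
    return(list(labels = rep(1L, length(lifespans)), medoids = c(x[1], x[1]),
                boundary = NA_real_, cost = 0, degenerate = TRUE))
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cost_side <- function(v) {
    med <- v[ceiling(length(v) / 2)]   # lower median is an optimal medoid
    c(cost = sum(abs(v - med)), medoid = med)
  }
  best <- NULL
  for (s in seq_len(n - 1)) {
    lo <- cost_side(xs[1:s]); hi <- cost_side(xs[(s + 1):n])
    tot <- lo["cost"] + hi["cost"]
    if (is.null(best) || tot < best$cost)
      best <- list(split = s, cost = unname(tot),
                   medoids = unname(c(lo["medoid"], hi["medoid"])))
  }
  boundary <- (xs[best$split] + xs[best$split + 1]) / 2
  labels <- rep(NA_integer_, length(lifespans))
  labels[!is.na(lifespans)] <- ifelse(x <= xs[best$split], 1L, 2L)
  list(labels = labels, medoids = best$medoids, boundary = boundary,
       cost = best$cost, degenerate = FALSE)
}

#' Cross association direction with selection intensity (IU/RU/ID/RD)
#'
#' IU: positively longevity-related, intensified (k > 1); RU: positive,
#' relaxed (k < 1); ID: negative, intensified; RD: negative, relaxed.
#' k exactly 1 is unclassified.  The strong flag marks k >= `k_strong` or
#' k <= `1/k_strong` (symmetric on the log scale).
#'
#' @param associations Gene table from [call_longevity_genes()] (needs
#'   `gene`, `direction`), or any data.frame with those columns.
#' @param selection_table data.frame with `gene`, `k` and optionally `p`.
#' @param k_strong Strong-selection threshold (default 10).
#' @param p_cut Optional filter on the selection-test P.
#' @param drop_conflicts Exclude genes with conflicting directions
#'   (default; they are returned flagged otherwise).
#' @return data.frame: `gene`, `direction`, `selection`, `class`, `k`,
#'   `strong`.
#' @export
classify_genes <- function(associations, selection_table, k_strong = 10,
                           p_cut = NULL, drop_conflicts = TRUE) {
  selection_table <- validate_selection_table(selection_table)
  df <- merge(associations[, c("gene", "direction")],
              selection_table, by = "gene")
  if (!is.null(p_cut) && !is.null(df$p)) df <- df[!is.na(df$p) & df$p < p_cut, ]
  conflict <- df$direction %in% "conflict"
  if (drop_conflicts) df <- df[!conflict, , drop = FALSE]
  df <- df[df$direction %in% c("positive", "negative"), , drop = FALSE]
  sel <- ifelse(df$k > 1, "intensified", ifelse(df$k < 1, "relaxed", NA))
  cls <- ifelse(is.na(sel), NA_character_,
                paste0(ifelse(sel == "intensified", "I", "R"),
                       ifelse(df$direction == "positive", "U", "D")))
  data.frame(gene = df$gene, direction = df$direction, selection = sel,
             class = cls, k = df$k,
             strong = df$k >= k_strong | df$k <= 1 / k_strong,
             stringsAsFactors = FALSE)
}

#' Summarize selection intensity by group
#'
#' @param selection_table data.frame with `gene`, `k`.
#' @param groups Optional named list of gene vectors defining groups (e.g.
#'   lifespan strata of the foreground set); default one group of all
#'   genes.
#' @param k_strong Strong-selection threshold.
#' @return data.frame per group: counts and fractions intensified, relaxed,
#'   at k = 1, and strong.
#' @export
summarize_selection <- function(selection_table, groups = NULL, k_strong = 10) {
  selection_table <- validate_selection_table(selection_table)
  if (is.null(groups)) groups <- list(all = selection_table$gene)
  rows <- lapply(names(groups), function(nm) {
    k <- selection_table$k[selection_table$gene %in% groups[[nm]]]
    k <- k[!is.na(k)]
    if (length(k) == 0) stop("empty group: ", nm)
    data.frame(group = nm, n = length(k),
               frac_intensified = mean(k > 1),
               frac_relaxed = mean(k < 1),
               frac_k1 = mean(k == 1),
               frac_strong = mean(k >= k_strong | k <= 1 / k_strong),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
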