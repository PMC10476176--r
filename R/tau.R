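#' Species-specificity index Tau
#'
#' For per-species expression values `v_1..v_N` (one tissue), with
#' `x_i = v_i / max_j v_j`, `tau = sum(1 - x_i) / (N - 1)`.  Tau is 0 for a
#' uniformly expressed gene and 1 for a gene expressed in a single species;
#' it is invariant to positive rescaling.  Masked species are excluded from
#' N.  Ties at the maximum each get `x = 1`.  A gene whose observed values
#' are all zero has undefined tau and is flagged, not scored 0.
#'
#' @param values Per-species expression values (>= 0; `NA` = masked).
#' @return `list(tau, n_species, class, defined)` with
#'   `class = "broad"` iff tau < 0.2 and `"specific"` iff tau > 0.8.
#' @export
tau_index <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("tau needs >= 2 observed species")
  if (any(v < 0)) stop("tau requires non-negative values")
  if (max(v) == 0)
    return(list(tau = NA_real_, n_species = length(v),
                class = NA_character_, defined = FALSE))
  x <- v / max(v)
  tau <- sum(1 - x) / (length(v) - 1)
  list(tau = tau, n_species = length(v), class = tau_class(tau),
       defined = TRUE)
}

tau_class <- function(tau, broad = 0.2, specific = 0.8) {
  ifelse(tau < broad, "broad", ifelse(tau > specific, "specific", "intermediate"))
}

#' Tau for every gene of a species-mean matrix
#'
#' @param mat Gene x species matrix (from [species_mean()]).
#' @param min_species Genes observed in fewer species get `NA` tau.
#' @return data.frame with `gene`, `tau`, `n_species`, `class`.
#' @export
tau_table <- function(mat, min_species = 2) {
  n_obs <- rowSums(!is.na(mat))
  mx <- apply(mat, 1, function(v) max(v, na.rm = TRUE))
  tau <- rep(NA_real_, nrow(mat))
  ok <- n_obs >= max(2, min_species) & mx > 0
  if (any(ok)) {
    xs <- mat[ok, , drop = FALSE] / mx[ok]
    tau[ok] <- rowSums(1 - xs, na.rm = TRUE) / (n_obs[ok] - 1)
  }
  data.frame(gene = rownames(mat), tau = tau, n_species = n_obs,
             class = ifelse(is.na(tau), NA_character_, tau_class(tau)),
             stringsAsFactors = FALSE)
}
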