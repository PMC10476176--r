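#' Read a life-history table from TSV
#'
#' Columns: `species`, `AW` (adult weight, g), `ML` (maximum lifespan, yr),
#' `FTM` (female time to maturity, yr), optionally `MLres`, `FTMres` and
#' per-trait status columns (`ML_status` in `observed|missing|imputed`).
#' Traits must be strictly positive where observed.
#'
#' @param path TSV path.
#' @return A `life_history` data.frame.
#' @export
read_life_history <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_life_history(tab)
}

#' Coerce a data.frame to a validated life-history table
#' @param tab data.frame with at least `species`, `AW`, `ML`, `FTM`.
#' @return A `life_history` data.frame.
#' @export
as_life_history <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("species", "AW", "ML", "FTM")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("life-history table lacks: ", paste(miss, collapse = ", "))
  tab$species <- normalize_species(tab$species)
  if (anyDuplicated(tab$species)) stop("duplicate species in life-history table")
  for (tr in c("AW", "ML", "FTM")) {
    v <- tab[[tr]]
    if (any(!is.na(v) & v <= 0)) stop(tr, " must be strictly positive where observed")
    st_col <- paste0(tr, "_status")
    if (is.null(tab[[st_col]]))
      tab[[st_col]] <- ifelse(is.na(v), "missing", "observed")
  }
  class(tab) <- c("life_history", "data.frame")
  tab
}

#' Write a life-history table to TSV
#' @param tab A `life_history` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_history <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allometric residual longevity traits
#'
#' Longevity traits scale with body mass, so absolute ML/FTM confound size
#' with pace of life.  `MLres` is the residual of a log-log ordinary
#' least-squares regression of ML on adult weight over a reference set
#' (defaults to the complete cases of `tab` itself); `FTMres` analogously.
#' Residuals are dimensionless and, as differences of logs, independent of
#' the logarithm base up to a constant factor.
#'
#' @param tab A `life_history` table with observed AW and target traits.
#' @param reference Optional reference `life_history` table used to fit the
#'   allometric lines (the study fits on a large external compilation).
#' @param base Logarithm base (default `exp(1)`).
#' @return `tab` with `MLres`, `FTMres` columns; fitted coefficients are
#'   attached as attribute `"allometry"`.
#' @export
allometric_residuals <- function(tab, reference = NULL, base = exp(1)) {
  tab <- as_life_history(tab)
  ref <- if (is.null(reference)) tab else as_life_history(reference)
  lg <- function(v) log(v, base = base)
  coefs <- list()
  for (tr in c("ML", "FTM")) {
    cc <- !is.na(ref$AW) & !is.na(ref[[tr]])
    if (sum(cc) < 3) stop("fewer than 3 complete cases for ", tr, " ~ AW")
    fit <- stats::lm(lg(ref[[tr]][cc]) ~ lg(ref$AW[cc]))
    b <- unname(stats::coef(fit))
    coefs[[tr]] <- c(intercept = b[1], slope = b[2])
    res_col <- paste0(tr, "res")
    tab[[res_col]] <- lg(tab[[tr]]) - (b[1] + b[2] * lg(tab$AW))
  }
  attr(tab, "allometry") <- coefs
  tab
}

#' Pipeline configuration
#'
#' Bundles the thresholds and sizes used across stages, with the defaults
#' the analysis is calibrated to.  All randomized stages additionally take
#' an explicit seed, recorded in the run log.
#'
#' @param tau_broad Tau below which a gene is broadly expressed (0.2).
#' @param tau_specific Tau above which a gene is species-specific (0.8).
#' @param p_robust_cut Adjusted robust-P cutoff (0.005).
#' @param p_max_cut Adjusted max-P cutoff (0.05).
#' @param min_species Minimum species per gene (68 at full scale).
#' @param long_lived_ml Long-lived lifespan cutoff, years (30).
#' @param k_strong Strong-selection threshold on k (10; relaxed mirror 1/10).
#' @param n_perm Trait permutations for maxT adjustment.
#' @param n_draws Null draws for empirical set P values.
#' @param seed Base seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tau_broad = 0.2, tau_specific = 0.8,
                            p_robust_cut = 0.005, p_max_cut = 0.05,
                            min_species = 68, long_lived_ml = 30,
                            k_strong = 10, n_perm = 1000,
                            n_draws = 400000, seed = 1L) {
  stopifnot(tau_broad > 0, tau_broad < tau_specific, tau_specific < 1,
            p_robust_cut > 0, p_robust_cut < 1,
            p_max_cut > 0, p_max_cut < 1,
            min_species >= 1, long_lived_ml > 0, k_strong > 1,
            n_perm >= 1, n_draws >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Append key=value lines describing a run to a plain-text log.
write_run_log <- function(path, config, extra = list()) {
  vals <- c(unclass(config), extra)
  lines <- c(sprintf("timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(vals), function(nm)
               sprintf("%s=%s", nm, paste(format(vals[[nm]]), collapse = ",")),
               character(1)))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
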