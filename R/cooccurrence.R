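#' C-score of an incidence matrix
#'
#' The mean number of checkerboard units over all unordered genus pairs:
#' for genera i and j occupying `Ri` and `Rj` sites and co-occurring at `S`
#' sites, the pair contributes `(Ri - S)(Rj - S)` units; the C-score is the
#' average over the `P(P-1)/2` pairs. High values indicate segregated
#' (mutually exclusive) distributions.
#'
#' @param m Binary incidence matrix (sites in rows, genera in columns) with
#'   at least 2 genera.
#' @return The C-score.
#' @export
c_score <- function(m) {
  m <- unclass_incidence(m)
  if (!is_binary_matrix(m)) stop("incidence matrix must be binary")
  p <- ncol(m)
  if (p < 2L) stop_degenerate("C-score needs at least 2 genera")
  checkerboard_pair_total(m) / (p * (p - 1) / 2)
}

#' Standardized effect size against a null distribution
#'
#' `SES = (obs - null mean) / null sd`: the number of null standard
#' deviations between the observation and the null expectation. Under an
#' adequate null about 95% of SES values fall in (-2, 2); SES above 2
#' indicates non-random segregation, below -2 non-random aggregation.
#'
#' @param obs Observed statistic.
#' @param null A [null_distribution()].
#' @return The standardized effect size.
#' @export
ses <- function(obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$sd <= 0) stop("degenerate null: sd is zero")
  (obs - null$mean) / null$sd
}

#' C-score / SES co-occurrence analysis
#'
#' Computes the observed C-score of the (optionally trophic-subset)
#' community, simulates its null distribution under the fixed-fixed
#' sequential-swap null (both row and column sums preserved), and reports
#' the standardized effect size. SES > 2 indicates non-random segregation,
#' SES < -2 non-random aggregation.
#'
#' @param table A `community_table` or binary incidence matrix.
#' @param group Optional trophic group (PF, BF, FF, OP) to subset first.
#' @param n_sims Number of null matrices (default 10000).
#' @param seed Integer seed.
#' @param threshold Presence threshold for [to_incidence()].
#' @return List of class `cscore_result`: `c_obs`, `null`, `ses`, `n_taxa`,
#'   `n_sites`, `group`, `degenerate`.
#' @export
cooccurrence_analysis <- function(table, group = NULL, n_sims = 10000,
                                  seed = 1L, threshold = 1) {
  if (inherits(table, "community_table")) {
    if (!is.null(group)) table <- subset_trophic(table, group)
    inc <- to_incidence(table, threshold = threshold)
  } else {
    inc <- to_incidence(table, threshold = threshold)
  }
  m <- unclass_incidence(inc)
  if (ncol(m) < 2L)
    stop_degenerate("degenerate subset: co-occurrence needs at least 2 genera")
  c_obs <- c_score(m)
  null <- null_distribution(c_score, m, method = "fixed_fixed",
                            n_sims = n_sims, seed = seed)
  degen <- null$degenerate
  structure(list(c_obs = c_obs,
                 null = null,
                 ses = if (degen) NA_real_ else ses(c_obs, null),
                 n_taxa = ncol(m), n_sites = nrow(m),
                 group = group, n_sims = n_sims, seed = seed,
                 degenerate = degen),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, ...) {
  cat("Co-occurrence analysis",
      if (!is.null(x$group)) paste0(" [", x$group, "]"), "\n", sep = "")
  cat(sprintf("  C-score = %.4f, null %.4f (SD %.4f), SES = %.2f\n",
              x$c_obs, x$null$mean, x$null$sd, x$ses))
  if (x$degenerate) {
    cat("  null distribution degenerate; SES unavailable\n")
  } else if (x$ses > 2) {
    cat("  SES > 2: non-random segregation\n")
  } else if (x$ses < -2) {
    cat("  SES < -2: non-random aggregation\n")
  } else {
    cat("  |SES| <= 2: consistent with random co-occurrence\n")
  }
  invisible(x)
}

#' Tabulate co-occurrence results
#'
#' One row per analysis unit (and optional trophic group) with the observed
#' C-score, null moments, SES and provenance.
#'
#' @param results Named list of `cscore_result` objects.
#' @return A data frame.
#' @export
cooccurrence_report <- function(results) {
  stopifnot(length(results) > 0)
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(unit = nm, group = x$group %||% "all",
               c_obs = x$c_obs, null_mean = x$null$mean,
               null_sd = x$null$sd, ses = x$ses,
               n_taxa = x$n_taxa, n_sites = x$n_sites,
               n_sims = x$n_sims, seed = x$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
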