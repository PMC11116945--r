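#' Published EMS summary statistics for a soil nematode survey
#'
#' Summary statistics of an elements-of-metacommunity-structure analysis of
#' soil nematode communities surveyed at four stations and three land
#' covers in Northeast China, at the local (per-station) and regional
#' (pooled) scales: embedded-absence and replacement counts with their
#' null-model moments and p-values, Morisita's boundary index, and the
#' published structure label for each of the 15 analysis units. Shipped as
#' plain text and used to validate the classification decision tree and the
#' z-score arithmetic against an independent, published analysis.
#'
#' @return Data frame with one row per analysis unit; columns `scale`,
#'   `land_cover`, `site`, coherence (`abs`, `coh_p`, `coh_mean`, `coh_sd`,
#'   `coh_z`), turnover (`rep`, `tur_p`, `tur_mean`, `tur_sd`, `tur_z`),
#'   boundary (`morisita_i`, `bnd_p`) and `structure`.
#' @export
reference_ems_stats <- function() {
  path <- system.file("extdata", "ems_reference_stats.csv",
                      package = "nemastruct", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify one row of published EMS statistics
#'
#' Feeds the printed observed counts, null means and p-values of one
#' reference row through [classify_structure()], so the decision tree can
#' be checked against the published labels without re-running any null
#' model.
#'
#' @param row One-row data frame in the layout of [reference_ems_stats()].
#' @param alpha Significance level (default 0.05).
#' @return The structure label.
#' @export
classify_reference_row <- function(row, alpha = 0.05) {
  coh <- list(obs = row$abs, null_mean = row$coh_mean, p = row$coh_p)
  tur <- list(obs = row$rep, null_mean = row$tur_mean, p = row$tur_p)
  bnd <- list(morisita_i = row$morisita_i, p = row$bnd_p)
  classify_structure(coh, tur, bnd, alpha = alpha)
}
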