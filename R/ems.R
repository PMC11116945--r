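#' Embedded absences of an ordered incidence matrix
#'
#' An embedded absence is a 0 lying strictly inside a genus' range (between
#' its first and last presence in row order) on the ordinated matrix. In the
#' default `both_axes` mode the analogous gaps inside each site's range
#' (along the column order) are added; `columns_only` counts genus ranges
#' alone. Few embedded absences mean coherent, uninterrupted ranges.
#'
#' @param om Ordinated binary incidence matrix (see
#'   [reciprocal_averaging()]).
#' @param mode `"both_axes"` (default) or `"columns_only"`.
#' @return Integer count of embedded absences.
#' @export
embedded_absences <- function(om, mode = c("both_axes", "columns_only")) {
  mode <- match.arg(mode)
  m <- unclass_incidence(om)
  out <- sum_range_gaps(m)
  if (mode == "both_axes") out <- out + sum_range_gaps(t(m))
  out
}

# total zeros strictly inside column ranges
sum_range_gaps <- function(m) {
  total <- 0L
  for (j in seq_len(ncol(m))) {
    w <- which(m[, j] == 1)
    if (length(w)) total <- total + (w[length(w)] - w[1] + 1L - length(w))
  }
  unname(total)
}

#' Fill genus ranges of an ordered incidence matrix
#'
#' Sets embedded absences to 1: every cell between a genus' first and last
#' presence becomes a presence. Turnover is conventionally computed on this
#' filled matrix so that replacements reflect range boundaries, not range
#' gaps.
#'
#' @param om Ordinated binary incidence matrix.
#' @return Binary matrix with contiguous column ranges.
#' @export
fill_ranges <- function(om) {
  m <- unclass_incidence(om)
  for (j in seq_len(ncol(m))) {
    w <- which(m[, j] == 1)
    if (length(w) > 1L) m[w[1]:w[length(w)], j] <- 1
  }
  m
}

#' Replacements (turnover) of an ordered incidence matrix
#'
#' After filling ranges, counts over all genus pairs and site pairs the
#' instances where one genus is present at site a but not site b while the
#' other is present at b but not a. Each opposing (site pair, genus pair)
#' combination counts once; for a genus pair the count is
#' `|A_i \ A_j| * |A_j \ A_i|` on the filled ranges.
#'
#' @param om Ordinated binary incidence matrix.
#' @param fill Fill ranges first (default TRUE, the standard convention).
#' @return Integer replacement count.
#' @export
replacements <- function(om, fill = TRUE) {
  m <- unclass_incidence(om)
  if (fill) m <- fill_ranges(m)
  checkerboard_pair_total(m)
}

# sum over unordered column pairs of (Ri - Sij)(Rj - Sij)
checkerboard_pair_total <- function(m) {
  s <- crossprod(m)
  r <- colSums(m)
  cu <- (r - s) * t(r - s)   # (Ri - Sij) * (Rj - Sij)
  sum(cu[upper.tri(cu)])
}

#' Morisita boundary-clumping analysis
#'
#' Counts genus range boundaries per site (the sites holding each genus'
#' first and last occurrence both count) and measures their aggregation with
#' Morisita's index of dispersion
#' `I = n * sum(f_i (f_i - 1)) / (F (F - 1))` where `f_i` is the boundary
#' count at site i and `F` their total. `I` near 1 indicates random
#' boundaries (Gleasonian), significantly above 1 clumped boundaries
#' (Clementsian), significantly below 1 evenly spaced boundaries. The
#' dispersion chi-squared statistic with `df = n - 1` gives the p-value,
#' one-tailed toward the observed side of 1.
#'
#' @param om Ordinated binary incidence matrix with at least 2 sites.
#' @return List of class `boundary_result`: `morisita_i`, `chi2`, `df`, `p`,
#'   and the per-site `boundary_counts`.
#' @export
morisita_boundary <- function(om) {
  m <- unclass_incidence(om)
  n <- nrow(m)
  if (n < 2L) stop_degenerate("boundary clumping needs at least 2 sites")
  f <- numeric(n)
  for (j in seq_len(ncol(m))) {
    w <- which(m[, j] == 1)
    if (length(w)) {
      f[w[1]] <- f[w[1]] + 1
      f[w[length(w)]] <- f[w[length(w)]] + 1
    }
  }
  bigF <- sum(f)
  if (bigF < 2) stop_degenerate("fewer than 2 range boundaries")
  i_val <- n * sum(f * (f - 1)) / (bigF * (bigF - 1))
  expected <- bigF / n
  chi2 <- sum((f - expected)^2 / expected)
  df <- n - 1L
  p <- if (i_val >= 1) stats::pchisq(chi2, df, lower.tail = FALSE)
       else stats::pchisq(chi2, df, lower.tail = TRUE)
  structure(list(morisita_i = i_val, chi2 = chi2, df = df, p = p,
                 boundary_counts = f),
            class = "boundary_result")
}

#' Package observed statistic, null moments and significance as one element
#'
#' Convenience constructor used both for freshly simulated elements and for
#' published summary statistics (observed value, null mean/SD, p). When `p`
#' is missing it is computed with [z_and_p()].
#'
#' @param obs Observed count.
#' @param null_mean,null_sd Null-distribution moments.
#' @param p Optional p-value (printed tables carry their own).
#' @param null Optional full [null_distribution()].
#' @return List of class `ems_element` with `obs`, `null_mean`, `null_sd`,
#'   `z`, `p`.
#' @export
ems_element <- function(obs, null_mean, null_sd, p = NULL, null = NULL) {
  zp <- z_and_p(obs, mean = null_mean, sd = null_sd)
  structure(list(obs = obs, null_mean = null_mean, null_sd = null_sd,
                 z = zp$z, p = p %||% zp$p, null = null),
            class = "ems_element")
}

#' Classify metacommunity structure from the three EMS elements
#'
#' The decision tree of the elements-of-metacommunity-structure framework.
#' Non-significant coherence gives a Random structure; significantly more
#' embedded absences than expected give Checkerboard. With positive
#' coherence (fewer absences than expected), significant turnover splits
#' into Nested (replacements below the null mean) versus gradient structures
#' (above), and boundary clumping separates Clementsian (`I` significantly
#' above 1), Evenly spaced (significantly below 1) and Gleasonian
#' (indistinguishable from 1); nested subtypes are clumped, stochastic or
#' hyperdispersed loss on the same rule. Non-significant turnover yields the
#' corresponding Quasi- structure, the direction of the replacement count
#' against its null mean choosing the branch.
#'
#' @param coh Coherence element ([ems_element()]): embedded absences.
#' @param tur Turnover element: replacements.
#' @param bnd Boundary result ([morisita_boundary()]) or a list with
#'   `morisita_i` and `p`.
#' @param alpha Significance level (default 0.05).
#' @return Character scalar, one of the structure labels.
#' @export
classify_structure <- function(coh, tur, bnd, alpha = 0.05) {
  stopifnot(is.numeric(coh$p), is.numeric(tur$p), is.numeric(bnd$p),
            is.numeric(bnd$morisita_i))
  if (coh$p >= alpha) return("Random")
  if (coh$obs > coh$null_mean) return("Checkerboard")

  clumping <- if (bnd$p < alpha && bnd$morisita_i > 1) "clumped"
              else if (bnd$p < alpha && bnd$morisita_i < 1) "hyperdispersed"
              else "random"
  quasi <- tur$p >= alpha
  nested <- tur$obs < tur$null_mean

  label <- if (nested) {
    switch(clumping,
           clumped = "nested (clumped loss)",
           hyperdispersed = "nested (hyperdispersed loss)",
           random = "nested (stochastic loss)")
  } else {
    switch(clumping,
           clumped = "Clementsian",
           hyperdispersed = "evenly spaced",
           random = "Gleasonian")
  }
  if (quasi) paste0("Quasi-", label)
  else if (nested) paste0("N", substring(label, 2)) # capitalize Nested
  else if (label == "evenly spaced") "Evenly spaced"
  else label
}

#' Run the full EMS analysis on one analysis unit
#'
#' Composes subsetting, incidence conversion, reciprocal-averaging
#' ordination, the coherence and turnover null tests and boundary clumping,
#' and returns the structure label with full provenance. Coherence and
#' turnover are evaluated against the same set of null matrices (each
#' re-ordinated before counting), drawn with the row-fixed null by default.
#'
#' @param table A `community_table`; if `land_cover` is NULL the table is
#'   analyzed as-is.
#' @param land_cover,scale,site Passed to [subset_community()].
#' @param n_sims Number of null matrices (default 1000).
#' @param seed Integer seed.
#' @param mode Embedded-absence counting mode (see [embedded_absences()]).
#' @param method Null model for the EMS elements (default `"row_fixed"`).
#' @param alpha Significance level for the classification.
#' @param threshold Presence threshold for [to_incidence()].
#' @return List of class `ems_result`: `ordination`, `coherence`,
#'   `turnover`, `boundary`, `label`, and settings.
#' @export
ems_pipeline <- function(table, land_cover = NULL,
                         scale = c("regional", "local"), site = NULL,
                         n_sims = 1000, seed = 1L,
                         mode = c("both_axes", "columns_only"),
                         method = c("row_fixed", "fixed_fixed"),
                         alpha = 0.05, threshold = 1) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!is.null(land_cover))
    table <- subset_community(table, land_cover, scale, site)
  inc <- to_incidence(table, threshold = threshold)
  if (ncol(inc) < 2L)
    stop_degenerate("degenerate subset: fewer than 2 genera with presences")
  ord <- reciprocal_averaging(inc)
  om <- ord$ordered_matrix

  abs_obs <- embedded_absences(om, mode = mode)
  rep_obs <- replacements(om)

  sims <- simulate_ems_nulls(inc, method, n_sims, seed, mode)
  coh <- ems_element(abs_obs, mean(sims$abs), stats::sd(sims$abs),
                     null = null_dist(sims$abs, method, seed))
  tur <- ems_element(rep_obs, mean(sims$rep), stats::sd(sims$rep),
                     null = null_dist(sims$rep, method, seed))
  bnd <- morisita_boundary(om)
  label <- classify_structure(coh, tur, bnd, alpha = alpha)

  structure(list(ordination = ord, coherence = coh, turnover = tur,
                 boundary = bnd, label = label,
                 settings = list(n_sims = n_sims, seed = seed, mode = mode,
                                 method = method, alpha = alpha,
                                 threshold = threshold,
                                 land_cover = land_cover, scale = scale,
                                 site = site)),
            class = "ems_result")
}

# one pass of null matrices scored for both coherence and turnover;
# each null matrix is re-ordinated before counting, as the observed one is.
simulate_ems_nulls <- function(inc, method, n_sims, seed, mode) {
  m <- unclass_incidence(inc)
  abs_v <- numeric(n_sims)
  rep_v <- numeric(n_sims)
  if (method == "fixed_fixed") {
    fill <- sum(m)
    set.seed(derive_seed(seed, 0L))
    im <- m; storage.mode(im) <- "integer"
    state <- cpp_swap_chain(im, as.numeric(10 * fill))
  }
  for (i in seq_len(n_sims)) {
    if (method == "row_fixed") {
      null_m <- randomize_row_fixed(m, seed = derive_seed(seed, i))
    } else {
      state <- cpp_swap_chain(state, as.numeric(sum(m)))
      null_m <- matrix(as.numeric(state), nrow(m), ncol(m))
    }
    null_om <- order_by_ra(null_m)
    abs_v[i] <- embedded_absences(null_om, mode = mode)
    rep_v[i] <- replacements(null_om)
  }
  list(abs = abs_v, rep = rep_v)
}

#' @export
print.ems_result <- function(x, ...) {
  cat("EMS analysis", if (!is.null(x$settings$land_cover))
    paste0(" [", x$settings$scale, " / ", x$settings$land_cover,
           if (!is.null(x$settings$site)) paste0(" / ", x$settings$site),
           "]"), "\n", sep = "")
  cat(sprintf("  Coherence: Abs = %.0f, null %.2f (SD %.2f), z = %.2f, p = %.3g\n",
              x$coherence$obs, x$coherence$null_mean, x$coherence$null_sd,
              x$coherence$z, x$coherence$p))
  cat(sprintf("  Turnover:  Rep = %.0f, null %.2f (SD %.2f), z = %.2f, p = %.3g\n",
              x$turnover$obs, x$turnover$null_mean, x$turnover$null_sd,
              x$turnover$z, x$turnover$p))
  cat(sprintf("  Boundary:  I = %.2f, chi2 = %.2f (df %d), p = %.3g\n",
              x$boundary$morisita_i, x$boundary$chi2, x$boundary$df,
              x$boundary$p))
  cat("  Structure: ", x$label, "\n", sep = "")
  invisible(x)
}

#' Tabulate EMS results in the standard report layout
#'
#' One row per analysis unit with the coherence, turnover and boundary
#' statistics and the structure label, mirroring the conventional published
#' layout (Abs, p, Mean, SD, Z | Rep, p, Mean, SD, Z | I, p | structure).
#'
#' @param results Named list of `ems_result` objects.
#' @return A data frame.
#' @export
ems_report <- function(results) {
  stopifnot(length(results) > 0)
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(unit = nm,
               Abs = x$coherence$obs, coh_p = x$coherence$p,
               coh_mean = x$coherence$null_mean, coh_sd = x$coherence$null_sd,
               coh_z = x$coherence$z,
               Rep = x$turnover$obs, tur_p = x$turnover$p,
               tur_mean = x$turnover$null_mean, tur_sd = x$turnover$null_sd,
               tur_z = x$turnover$z,
               I = x$boundary$morisita_i, bnd_p = x$boundary$p,
               structure = x$label,
               seed = x$settings$seed, n_sims = x$settings$n_sims,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
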