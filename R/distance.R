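#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_k - y_k| / sum(x_k + y_k)` on abundance vectors, bounded
#' in [0, 1]. Computed with \pkg{vegan}'s distance machinery.
#'
#' @param counts Nonnegative abundance matrix (samples in rows) or a
#'   `community_table`.
#' @return A `distance_matrix` object (symmetric, zero diagonal).
#' @export
bray_curtis <- function(counts) {
  m <- if (inherits(counts, "community_table")) counts$counts else
    as_count_matrix(counts)
  if (any(m < 0)) stop("abundances must be nonnegative")
  if (any(rowSums(m) == 0)) {
    bad <- rownames(m)[rowSums(m) == 0] %||% which(rowSums(m) == 0)
    stop("all-zero sample row(s): ", paste(bad, collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  distance_matrix(d, kind = "bray_curtis")
}

#' Euclidean distance on (standardized) environmental variables
#'
#' Variables are standardized to zero mean and unit variance by default so
#' that each contributes equally. Zero-variance variables cannot be
#' standardized and are dropped with a warning.
#'
#' @param env Data frame or matrix of per-sample environmental variables; a
#'   `sample_id` column, if present, is used for labels.
#' @param standardize Standardize variables first (default TRUE).
#' @return A `distance_matrix` object.
#' @export
euclidean_env <- function(env, standardize = TRUE) {
  env <- as.data.frame(env)
  labels <- if ("sample_id" %in% names(env)) env$sample_id else rownames(env)
  num <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (!ncol(num)) stop("no numeric environmental variables")
  if (anyNA(num)) stop("environmental records must be complete (no NA)")
  x <- as.matrix(num)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      if (!ncol(x)) stop("no variables left after dropping zero variance")
    }
    x <- scale(x)
  }
  d <- as.matrix(stats::dist(x))
  rownames(d) <- colnames(d) <- labels
  distance_matrix(d, kind = "euclidean_env")
}

#' Geographic distance between sampling locations
#'
#' Default `great_circle` mode: haversine distance in kilometres on a sphere
#' of radius 6371 km (via \pkg{geosphere}); `euclidean_degrees` treats
#' (longitude, latitude) as plane coordinates.
#'
#' @param lonlat Two-column matrix or data frame: longitude, latitude in
#'   decimal degrees (columns named `longitude`/`latitude` or the first two
#'   columns).
#' @param mode `"great_circle"` (default) or `"euclidean_degrees"`.
#' @return A `distance_matrix` object (km for great-circle mode).
#' @export
geographic_distance <- function(lonlat,
                                mode = c("great_circle",
                                         "euclidean_degrees")) {
  mode <- match.arg(mode)
  ll <- as.data.frame(lonlat)
  labels <- if ("sample_id" %in% names(ll)) ll$sample_id else rownames(ll)
  cn <- names(ll)
  lon <- if ("longitude" %in% cn) ll$longitude else ll[[1]]
  lat <- if ("latitude" %in% cn) ll$latitude else ll[[2]]
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range: need |lat| <= 90 and |lon| <= 180")
  if (mode == "great_circle") {
    d <- geosphere::distm(cbind(lon, lat),
                          fun = function(a, b)
                            geosphere::distHaversine(a, b, r = 6371000)) / 1000
  } else {
    d <- as.matrix(stats::dist(cbind(lon, lat)))
  }
  rownames(d) <- colnames(d) <- labels
  distance_matrix(d, kind = if (mode == "great_circle") "geographic"
                            else "geographic_degrees")
}

distance_matrix <- function(d, kind) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  d[abs(d) < .Machine$double.eps^ 0.75] <- 0
  structure(d, kind = kind, class = c("distance_matrix", class(d)))
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices (Spearman
#' rank correlation by default) and assesses significance by permuting the
#' row/column labels of the second matrix. The default alternative is
#' one-tailed positive (distance decay: larger environmental or geographic
#' separation, larger community dissimilarity), with
#' `p = (1 + #[r_perm >= r_obs]) / (1 + n_perm)`.
#'
#' @param d1,d2 `distance_matrix` objects (or plain symmetric matrices) of
#'   the same size (at least 4 objects).
#' @param method Correlation method (`"spearman"` default, or `"pearson"`).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `seed`,
#'   `method`, `alternative`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 9999, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 objects")
  if (!all(dim(d1) == dim(d2)))
    stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrix labels do not match")
  ut <- upper.tri(d1)
  x <- d1[ut]
  if (stats::sd(d2[ut]) == 0 || stats::sd(x) == 0)
    stop("degenerate distance matrix: constant distances, correlation undefined")
  r_obs <- stats::cor(x, d2[ut], method = method)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_p <- stats::cor(x, d2[perm, perm][ut], method = method)
    hit <- if (alternative == "greater") r_p >= r_obs
           else abs(r_p) >= abs(r_obs)
    if (isTRUE(hit)) count <- count + 1L
  }
  structure(list(r = r_obs, p = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, method = method,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.3f, p = %.4f (%d permutations)\n",
              x$method, x$alternative, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Mantel report for a set of analysis units
#'
#' For each unit, correlates community Bray-Curtis dissimilarity with the
#' environmental Euclidean distance and the geographic distance, mirroring
#' the conventional (Env r, p | Spa r, p) layout.
#'
#' @param units Named list; each element a list with `table`
#'   (`community_table`) and `env` (aligned env data frame).
#' @param n_perm,seed,geo_mode Passed through to the distance and Mantel
#'   machinery.
#' @return A data frame with one row per unit.
#' @export
mantel_report <- function(units, n_perm = 9999, seed = 1L,
                          geo_mode = "great_circle") {
  rows <- lapply(names(units), function(nm) {
    u <- units[[nm]]
    dc <- bray_curtis(u$table)
    env_vars <- u$env[, intersect(c("SM", "ST", "pH", "STC", "STN", "STP"),
                                  names(u$env)), drop = FALSE]
    de <- euclidean_env(env_vars)
    dg <- geographic_distance(u$table$sample_meta[, c("longitude", "latitude")],
                              mode = geo_mode)
    rownames(de) <- colnames(de) <- rownames(as.matrix(dc))
    rownames(dg) <- colnames(dg) <- rownames(as.matrix(dc))
    m_env <- mantel_test(dc, de, n_perm = n_perm,
                         seed = derive_seed(seed, 1L))
    m_spa <- mantel_test(dc, dg, n_perm = n_perm,
                         seed = derive_seed(seed, 2L))
    data.frame(unit = nm, env_r = m_env$r, env_p = m_env$p,
               spa_r = m_spa$r, spa_p = m_spa$p,
               n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
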