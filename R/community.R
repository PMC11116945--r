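#' Trophic groups and land covers used throughout
#'
#' Nematode feeding guilds: plant parasites (PF), bacterivores (BF),
#' fungivores (FF) and omnivores-predators (OP); land covers of the emulated
#' survey design.
#'
#' @name domain-levels
#' @keywords internal
NULL

trophic_groups <- function() c("PF", "BF", "FF", "OP")
land_covers    <- function() c("farmland", "grassland", "woodland")

#' Construct a community table
#'
#' A community table couples a samples-by-genera count matrix with per-sample
#' metadata (site, land cover, year, replicate, coordinates) and per-genus
#' metadata (trophic group). It is the input to every analysis stage.
#'
#' @param counts Nonnegative integer matrix, samples in rows, genera in
#'   columns. Dimnames are taken from the metadata if absent.
#' @param sample_meta Data frame with columns `sample_id`, `site`,
#'   `land_cover`, `year`, `replicate`, `longitude`, `latitude`; one row per
#'   row of `counts`.
#' @param genus_meta Data frame with columns `genus_id`, `trophic_group`
#'   (one of PF, BF, FF, OP); one row per column of `counts`.
#' @return An object of class `community_table`.
#' @export
community_table <- function(counts, sample_meta, genus_meta) {
  counts <- as_count_matrix(counts)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  genus_meta <- as.data.frame(genus_meta, stringsAsFactors = FALSE)

  need_s <- c("sample_id", "site", "land_cover", "year", "replicate",
              "longitude", "latitude")
  miss <- setdiff(need_s, names(sample_meta))
  if (length(miss))
    stop("sample_meta is missing column(s): ", paste(miss, collapse = ", "))
  need_g <- c("genus_id", "trophic_group")
  miss <- setdiff(need_g, names(genus_meta))
  if (length(miss))
    stop("genus_meta is missing column(s): ", paste(miss, collapse = ", "))

  if (nrow(counts) != nrow(sample_meta))
    stop("counts has ", nrow(counts), " rows but sample_meta has ",
         nrow(sample_meta), " records")
  if (ncol(counts) != nrow(genus_meta))
    stop("counts has ", ncol(counts), " columns but genus_meta has ",
         nrow(genus_meta), " records")
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample_id in sample_meta: ",
         paste(unique(sample_meta$sample_id[duplicated(sample_meta$sample_id)]),
               collapse = ", "))
  if (anyDuplicated(genus_meta$genus_id))
    stop("duplicate genus_id in genus_meta")
  if (any(is.na(counts)) || any(counts < 0))
    bad_counts_error(counts)
  if (any(counts != round(counts)))
    stop("counts must be integers")
  bad <- !genus_meta$trophic_group %in% trophic_groups()
  if (any(bad))
    stop("unknown trophic group(s): ",
         paste(unique(genus_meta$trophic_group[bad]), collapse = ", "),
         " (expected PF, BF, FF, OP)")

  rownames(counts) <- sample_meta$sample_id
  colnames(counts) <- genus_meta$genus_id
  structure(list(counts = counts, sample_meta = sample_meta,
                 genus_meta = genus_meta),
            class = "community_table")
}

bad_counts_error <- function(counts) {
  idx <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1, , drop = TRUE]
  stop("invalid count at row ", rownames(counts)[idx[1]] %||% idx[1],
       " (", idx[1], "), column ", colnames(counts)[idx[2]] %||% idx[2],
       " (", idx[2], "): counts must be nonnegative and non-missing")
}

#' @export
print.community_table <- function(x, ...) {
  cat("Community table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " genera\n", sep = "")
  cat("  sites:       ", paste(unique(x$sample_meta$site), collapse = ", "),
      "\n", sep = "")
  cat("  land covers: ",
      paste(unique(x$sample_meta$land_cover), collapse = ", "), "\n", sep = "")
  tg <- table(x$genus_meta$trophic_group)
  cat("  trophic groups: ",
      paste(names(tg), tg, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert counts to a pruned presence-absence (incidence) matrix
#'
#' Entries become 1 where the count meets `threshold`; rows and columns that
#' end up all-zero are removed, and the removed labels are recorded as
#' attributes `dropped_rows` / `dropped_cols`.
#'
#' @param table A `community_table` or a nonnegative count matrix.
#' @param threshold Minimum count treated as a presence (default 1).
#' @return A binary matrix of class `incidence_matrix` with row and column
#'   labels preserved.
#' @export
to_incidence <- function(table, threshold = 1) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  m <- if (inherits(table, "community_table")) table$counts else
    as_count_matrix(table)
  if (length(m) == 0L) stop_degenerate("empty community matrix")
  inc <- (m >= threshold) * 1
  keep_r <- rowSums(inc) > 0
  keep_c <- colSums(inc) > 0
  out <- inc[keep_r, keep_c, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop_degenerate("degenerate matrix: no presences remain after pruning")
  structure(out, class = c("incidence_matrix", class(out)),
            dropped_rows = rownames(inc)[!keep_r] %||% which(!keep_r),
            dropped_cols = colnames(inc)[!keep_c] %||% which(!keep_c))
}

#' Subset a community table by land cover and spatial scale
#'
#' The survey design defines two scales: each site on its own is the local
#' scale; all sites pooled form the regional scale. Sampling years are pooled
#' by default (`years = NULL`).
#'
#' @param table A `community_table`.
#' @param land_cover One of `farmland`, `grassland`, `woodland` (or any level
#'   present in the table).
#' @param scale `"regional"` (all sites) or `"local"` (one site).
#' @param site Site name; required when `scale = "local"`.
#' @param years Optional vector of years to retain; default keeps all.
#' @param drop_empty_genera Drop genera with zero total count in the subset
#'   (default TRUE).
#' @return A `community_table` restricted to the requested samples.
#' @export
subset_community <- function(table, land_cover,
                             scale = c("regional", "local"), site = NULL,
                             years = NULL, drop_empty_genera = TRUE) {
  stopifnot(inherits(table, "community_table"))
  scale <- match.arg(scale)
  sm <- table$sample_meta
  if (!land_cover %in% sm$land_cover)
    stop("unknown land cover: '", land_cover, "' (have: ",
         paste(unique(sm$land_cover), collapse = ", "), ")")
  keep <- sm$land_cover == land_cover
  if (scale == "local") {
    if (is.null(site)) stop("site is required at the local scale")
    if (!site %in% sm$site)
      stop("unknown site: '", site, "' (have: ",
           paste(unique(sm$site), collapse = ", "), ")")
    keep <- keep & sm$site == site
  }
  if (!is.null(years)) keep <- keep & sm$year %in% years
  if (!any(keep)) stop_degenerate("no samples match the requested subset")
  counts <- table$counts[keep, , drop = FALSE]
  gm <- table$genus_meta
  if (drop_empty_genera) {
    keep_g <- colSums(counts) > 0
    counts <- counts[, keep_g, drop = FALSE]
    gm <- gm[keep_g, , drop = FALSE]
  }
  community_table(counts, sm[keep, , drop = FALSE], gm)
}

#' Subset a community table to one trophic group
#'
#' Retains only the genera labeled with the requested feeding guild; sample
#' rows are unchanged.
#'
#' @param table A `community_table`.
#' @param group One of `"PF"`, `"BF"`, `"FF"`, `"OP"`.
#' @return A `community_table` with the genus columns of that group.
#' @export
subset_trophic <- function(table, group) {
  stopifnot(inherits(table, "community_table"))
  if (!is.character(group) || length(group) != 1L ||
      !group %in% trophic_groups())
    stop("unknown trophic group: '", group,
         "' (expected one of PF, BF, FF, OP)")
  keep <- table$genus_meta$trophic_group == group
  if (!any(keep))
    stop_degenerate(paste0("degenerate subset: no genera in group ", group))
  community_table(table$counts[, keep, drop = FALSE], table$sample_meta,
                  table$genus_meta[keep, , drop = FALSE])
}

#' Validate an environment table against a community table
#'
#' @param env Data frame with `sample_id` and the environmental variables
#'   (SM, ST, pH, STC, STN, STP).
#' @param table A `community_table` whose samples the env table must cover.
#' @return The env table, row-aligned to the community table's samples.
#' @export
align_env <- function(env, table) {
  stopifnot(inherits(table, "community_table"), is.data.frame(env))
  if (!"sample_id" %in% names(env)) stop("env table lacks a sample_id column")
  if (anyDuplicated(env$sample_id)) stop("duplicate sample_id in env table")
  want <- table$sample_meta$sample_id
  missing <- setdiff(want, env$sample_id)
  if (length(missing))
    stop("env table is missing sample(s): ", paste(missing, collapse = ", "))
  env[match(want, env$sample_id), , drop = FALSE]
}
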