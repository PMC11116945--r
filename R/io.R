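#' Read a community table (and optional environment table) from text files
#'
#' Expects delimited text: a counts file whose first column is `sample_id`
#' and whose remaining header names are genera; a sample metadata file keyed
#' by `sample_id`; a two-or-more-column genus file mapping `genus_id` to
#' `trophic_group`; and optionally an environment file keyed by `sample_id`.
#' Mismatched or duplicated ids and malformed counts produce descriptive
#' errors naming the offending rows.
#'
#' @param counts_file,samples_file,genera_file,env_file File paths; comma
#'   (default) or tab delimited, chosen by `sep`.
#' @param sep Field separator.
#' @return A `community_table`, or a list `(community, env)` when
#'   `env_file` is given.
#' @export
read_community <- function(counts_file, samples_file, genera_file,
                           env_file = NULL, sep = ",") {
  cts <- utils::read.table(counts_file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(cts)[1] != "sample_id")
    stop("counts file must have 'sample_id' as its first column (got '",
         names(cts)[1], "')")
  ids <- cts$sample_id
  mat <- cts[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (anyNA(v))
      stop("non-numeric count in column '", names(mat)[j], "', row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    if (any(v < 0))
      stop("negative count in column '", names(mat)[j], "', row(s) ",
           paste(which(v < 0), collapse = ", "))
    mat[[j]] <- v
  }
  counts <- as.matrix(mat)
  rownames(counts) <- ids

  sm <- utils::read.table(samples_file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  gm <- utils::read.table(genera_file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_s <- setdiff(ids, sm$sample_id)
  if (length(missing_s))
    stop("sample metadata is missing sample(s): ",
         paste(missing_s, collapse = ", "))
  sm <- sm[match(ids, sm$sample_id), , drop = FALSE]
  missing_g <- setdiff(colnames(counts), gm$genus_id)
  if (length(missing_g))
    stop("genus metadata is missing genus/genera: ",
         paste(missing_g, collapse = ", "))
  gm <- gm[match(colnames(counts), gm$genus_id), , drop = FALSE]
  table <- community_table(counts, sm, gm)
  if (is.null(env_file)) return(table)
  env <- utils::read.table(env_file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  list(community = table, env = align_env(env, table))
}

#' Write a community table (and optional env table) as delimited text
#'
#' Inverse of [read_community()]: writes `<prefix>_counts.csv`,
#' `<prefix>_samples.csv`, `<prefix>_genera.csv` and, when `env` is given,
#' `<prefix>_env.csv` under `dir`.
#'
#' @param table A `community_table`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"community"`).
#' @param env Optional env data frame.
#' @param sep Field separator.
#' @return Invisibly, the written paths.
#' @export
write_community <- function(table, dir, prefix = "community", env = NULL,
                            sep = ",") {
  stopifnot(inherits(table, "community_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(dir, paste0(prefix, "_", x, ".csv"))
  cts <- data.frame(sample_id = rownames(table$counts),
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(cts, p("counts"), sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$sample_meta, p("samples"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(table$genus_meta, p("genera"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  paths <- c(p("counts"), p("samples"), p("genera"))
  if (!is.null(env)) {
    utils::write.table(env, p("env"), sep = sep, row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p("env"))
  }
  invisible(paths)
}

#' Read a YAML run configuration
#'
#' A configuration mirrors the arguments of [run_all()]: input paths
#' (`counts`, `samples`, `genera`, `env`), the output directory, and the
#' analysis settings (alpha, n_sims_ems, n_sims_cooc, n_perm_mantel, seeds,
#' counting mode, distance mode, land covers and sites). Paths must exist.
#'
#' @param path YAML file.
#' @return Named list of settings with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(alpha = 0.05, n_sims_ems = 1000, n_sims_cooc = 10000,
                   n_perm_mantel = 9999, seed = 1L, mode = "both_axes",
                   geo_mode = "great_circle", out_dir = "results",
                   by_trophic_group = TRUE)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("counts", "samples", "genera", "env")) {
    if (is.null(cfg[[nm]])) stop("config is missing input path '", nm, "'")
    if (!file.exists(cfg[[nm]]))
      stop("config input path does not exist: ", cfg[[nm]])
  }
  if (cfg$seed <= 0 || cfg$n_sims_ems < 2 || cfg$n_sims_cooc < 2)
    stop("seeds and simulation counts must be positive")
  cfg
}

#' Run the complete analysis over every scale and land cover
#'
#' Enumerates the analysis units of the survey design - each land cover at
#' each site (local scale) plus each land cover pooled over sites (regional
#' scale) - and produces the four standard reports: the EMS table (one row
#' per unit with coherence, turnover, boundary clumping and the structure
#' label), the Mantel table (community dissimilarity against environmental
#' and geographic distance), the co-occurrence table (C-score/SES overall
#' and per trophic group), and the permutation-importance table of regional
#' site scores. Units whose community is degenerate (too few genera or
#' samples) are skipped with a note in the returned `skipped` element.
#'
#' @param table A `community_table` covering the full design.
#' @param env Environment data frame aligned by `sample_id`.
#' @param out_dir Optional directory; when given, reports are written there
#'   as delimited text together with a `run_log.yaml` of all settings.
#' @param land_cover_set,site_set Units to analyze (defaults: all present).
#' @param n_sims_ems,n_sims_cooc,n_perm_mantel Simulation sizes.
#' @param seed Global seed; every unit derives its own stream.
#' @param alpha Significance level.
#' @param mode Embedded-absence counting mode.
#' @param geo_mode Geographic distance mode.
#' @param by_trophic_group Also run co-occurrence per trophic group.
#' @param min_taxa Minimum genera for a unit to be analyzed (default 5).
#' @return List with `ems`, `mantel`, `cooccurrence`, `importance` data
#'   frames, the underlying `ems_results`, and `skipped`.
#' @export
run_all <- function(table, env, out_dir = NULL,
                    land_cover_set = NULL, site_set = NULL,
                    n_sims_ems = 1000, n_sims_cooc = 10000,
                    n_perm_mantel = 9999, seed = 1L, alpha = 0.05,
                    mode = "both_axes", geo_mode = "great_circle",
                    by_trophic_group = TRUE, min_taxa = 5,
                    n_trees_importance = 500, n_perms_importance = 100) {
  stopifnot(inherits(table, "community_table"))
  env <- align_env(env, table)
  covers <- land_cover_set %||% unique(table$sample_meta$land_cover)
  sites <- site_set %||% unique(table$sample_meta$site)
  bad <- setdiff(covers, unique(table$sample_meta$land_cover))
  if (length(bad))
    stop("unknown land cover(s) in configuration: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(sites, unique(table$sample_meta$site))
  if (length(bad))
    stop("unknown site(s) in configuration: ", paste(bad, collapse = ", "))

  units <- data.frame(scale = character(), land_cover = character(),
                      site = character(), stringsAsFactors = FALSE)
  for (lc in covers) {
    for (st in sites)
      units <- rbind(units, data.frame(scale = "local", land_cover = lc,
                                       site = st))
    units <- rbind(units, data.frame(scale = "regional", land_cover = lc,
                                     site = NA_character_))
  }

  ems_results <- list(); cooc_results <- list(); mantel_units <- list()
  skipped <- character()
  for (k in seq_len(nrow(units))) {
    u <- units[k, ]
    nm <- if (u$scale == "local") paste(u$site, u$land_cover, sep = "/")
          else paste("regional", u$land_cover, sep = "/")
    sub <- tryCatch(
      subset_community(table, u$land_cover, u$scale,
                       site = if (u$scale == "local") u$site else NULL),
      nemastruct_degenerate = function(e) NULL)
    if (is.null(sub) || ncol(sub$counts) < min_taxa) {
      skipped <- c(skipped, nm); next
    }
    useed <- derive_seed(seed, k)
    ems_results[[nm]] <- ems_pipeline(sub, n_sims = n_sims_ems, seed = useed,
                                      mode = mode, alpha = alpha)
    mantel_units[[nm]] <- list(table = sub, env = align_env(env, sub))
    cooc_results[[nm]] <- cooccurrence_analysis(sub, n_sims = n_sims_cooc,
                                                seed = derive_seed(useed, 1L))
    if (by_trophic_group) {
      for (g in trophic_groups()) {
        res <- tryCatch(
          cooccurrence_analysis(sub, group = g, n_sims = n_sims_cooc,
                                seed = derive_seed(useed, match(g, trophic_groups()) + 1L)),
          nemastruct_degenerate = function(e) NULL)
        if (!is.null(res)) cooc_results[[paste(nm, g, sep = ":")]] <- res
      }
    }
  }
  if (!length(ems_results)) stop("no analyzable units")

  ems_tab <- ems_report(ems_results)
  mantel_tab <- mantel_report(mantel_units, n_perm = n_perm_mantel,
                              seed = derive_seed(seed, 9999L),
                              geo_mode = geo_mode)
  cooc_tab <- cooccurrence_report(cooc_results)

  # importance: regional site scores per land cover
  imp_rows <- list()
  for (lc in covers) {
    nm <- paste("regional", lc, sep = "/")
    if (!nm %in% names(ems_results)) next
    res <- ems_results[[nm]]
    sub <- mantel_units[[nm]]$table
    scores <- res$ordination$site_scores
    idx <- match(names(scores), sub$sample_meta$sample_id)
    vars <- cbind(align_env(env, sub)[idx, c("SM", "ST", "pH", "STC", "STN",
                                             "STP")],
                  longitude = sub$sample_meta$longitude[idx],
                  latitude = sub$sample_meta$latitude[idx])
    imp <- importance_analysis(scores, vars, n_trees = n_trees_importance,
                               n_perms = n_perms_importance,
                               seed = derive_seed(seed, 5000L + match(lc, covers)))
    tab <- imp$table
    tab$unit <- nm
    imp_rows[[nm]] <- tab[, c("unit", "variable", "importance", "p",
                              "signif", "rank")]
  }
  imp_tab <- if (length(imp_rows)) do.call(rbind, imp_rows) else NULL
  if (!is.null(imp_tab)) rownames(imp_tab) <- NULL

  out <- list(ems = ems_tab, mantel = mantel_tab, cooccurrence = cooc_tab,
              importance = imp_tab, ems_results = ems_results,
              skipped = skipped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ems_tab, file.path(out_dir, "ems_report.csv"),
                     row.names = FALSE)
    utils::write.csv(mantel_tab, file.path(out_dir, "mantel_report.csv"),
                     row.names = FALSE)
    utils::write.csv(cooc_tab, file.path(out_dir, "cooccurrence_report.csv"),
                     row.names = FALSE)
    if (!is.null(imp_tab))
      utils::write.csv(imp_tab, file.path(out_dir, "importance_report.csv"),
                       row.names = FALSE)
    yaml::write_yaml(list(version = as.character(utils::packageVersion("nemastruct")),
                          seed = seed, n_sims_ems = n_sims_ems,
                          n_sims_cooc = n_sims_cooc,
                          n_perm_mantel = n_perm_mantel, alpha = alpha,
                          mode = mode, geo_mode = geo_mode,
                          skipped = skipped),
                     file.path(out_dir, "run_log.yaml"))
  }
  out
}
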