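#' Define a synthetic metacommunity scenario
#'
#' Bundles the parameters of a structured metacommunity generator. Sites sit
#' at gradient positions 1..n_sites (one gradient unit between neighbours);
#' taxa receive ranges or occupancy rules according to `structure`, and the
#' boundary jitter `noise_sd` is expressed in gradient units.
#'
#' @param structure One of `clementsian`, `gleasonian`, `nested`,
#'   `checkerboard`, `evenly_spaced`, `random`, `segregated_pairs`,
#'   `aggregated_pairs`.
#' @param n_sites,n_taxa Matrix dimensions before pruning.
#' @param n_compartments Compartments for the Clementsian generator.
#' @param noise_sd Boundary jitter SD in gradient units (default 0.5).
#' @param fill_prob Bernoulli occupancy probability for `random`.
#' @param n_pairs Taxon pairs for the pair-based generators.
#' @param range_width Relative range-width interval for `gleasonian`
#'   (fractions of the gradient span).
#' @param seed Integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(structure = c("clementsian", "gleasonian",
                                             "nested", "checkerboard",
                                             "evenly_spaced", "random",
                                             "segregated_pairs",
                                             "aggregated_pairs"),
                               n_sites = 24, n_taxa = 30,
                               n_compartments = 3, noise_sd = 0.5,
                               fill_prob = 0.5, n_pairs = 10,
                               range_width = c(0.2, 0.5), seed = 1L) {
  structure <- match.arg(structure)
  if (n_sites < 2 || n_taxa < 2) stop("need at least 2 sites and 2 taxa")
  if (structure == "clementsian" && n_compartments > n_taxa)
    stop("more compartments than taxa")
  if (structure %in% c("checkerboard", "segregated_pairs",
                       "aggregated_pairs") && 2 * n_pairs > n_taxa + 1)
    stop("n_pairs too large for n_taxa")
  structure(list(structure = structure, n_sites = n_sites, n_taxa = n_taxa,
                 gradient = seq_len(n_sites),
                 n_compartments = n_compartments, noise_sd = noise_sd,
                 fill_prob = fill_prob, n_pairs = n_pairs,
                 range_width = range_width, seed = seed),
            class = "synthetic_scenario")
}

#' Generate a metacommunity with known structure
#'
#' Produces a `community_table` whose incidence pattern follows the
#' scenario's idealized structure: Clementsian compartments share jittered
#' range boundaries; Gleasonian ranges have independent centres and widths;
#' nested communities lose taxa in order of prevalence as site richness
#' falls; checkerboard/segregated pairs occupy mutually exclusive site sets
#' while aggregated pairs are co-placed; evenly spaced ranges have maximally
#' separated boundaries; random occupancy is independent Bernoulli.
#' Per-presence abundances follow a log-series-like rank-abundance model
#' scaled so each sample holds about 100 identified individuals.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `community_table` (samples = sites along the gradient).
#' @export
generate_metacommunity <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  set.seed(s$seed)
  inc <- switch(s$structure,
    clementsian = gen_clementsian(s),
    gleasonian = gen_gleasonian(s),
    nested = gen_nested(s),
    evenly_spaced = gen_evenly_spaced(s),
    random = matrix(stats::rbinom(s$n_sites * s$n_taxa, 1, s$fill_prob),
                    s$n_sites, s$n_taxa),
    checkerboard = gen_pairs(s, exclusive = TRUE),
    segregated_pairs = gen_pairs(s, exclusive = TRUE),
    aggregated_pairs = gen_pairs(s, exclusive = FALSE))
  counts <- abundances_from_incidence(inc, target_total = 100)
  synthetic_community(counts, s)
}

range_to_incidence <- function(lo, hi, n_sites) {
  # taxa in columns; presence where the integer gradient position is inside
  vapply(seq_along(lo), function(j)
    as.numeric(seq_len(n_sites) >= lo[j] & seq_len(n_sites) <= hi[j]),
    numeric(n_sites))
}

gen_clementsian <- function(s) {
  edges <- seq(0.5, s$n_sites + 0.5, length.out = s$n_compartments + 1)
  comp <- rep(seq_len(s$n_compartments), length.out = s$n_taxa)
  lo <- edges[comp] + stats::rnorm(s$n_taxa, 0, s$noise_sd)
  hi <- edges[comp + 1] + stats::rnorm(s$n_taxa, 0, s$noise_sd)
  range_to_incidence(pmin(lo, hi), pmax(lo, hi), s$n_sites)
}

gen_gleasonian <- function(s) {
  # ranges drawn wholly inside the gradient so boundaries fall uniformly;
  # truncation at the ends would otherwise mimic boundary clumping
  w <- stats::runif(s$n_taxa, s$range_width[1], s$range_width[2]) * s$n_sites
  lo <- stats::runif(s$n_taxa, 0.51, s$n_sites + 0.49 - w)
  range_to_incidence(lo, lo + w, s$n_sites)
}

gen_nested <- function(s) {
  # taxon j occupies the first k_j sites; prevalence declines with rank
  k <- round(seq(s$n_sites, 1, length.out = s$n_taxa))
  k <- pmax(1, pmin(s$n_sites, k + round(stats::rnorm(s$n_taxa, 0, s$noise_sd))))
  range_to_incidence(rep(1, s$n_taxa), k, s$n_sites)
}

gen_evenly_spaced <- function(s) {
  # equal widths, starts spread uniformly: boundaries maximally separated
  width <- max(1, round(s$n_sites / 3))
  lo <- seq(1, s$n_sites - width + 1, length.out = s$n_taxa)
  lo <- lo + stats::rnorm(s$n_taxa, 0, s$noise_sd)
  range_to_incidence(lo, lo + width - 1, s$n_sites)
}

gen_pairs <- function(s, exclusive) {
  inc <- matrix(0, s$n_sites, s$n_taxa)
  half <- floor(s$n_sites / 2)
  if (exclusive) {
    # segregation: pair members occupy mutually exclusive site sets
    for (k in seq_len(s$n_pairs)) {
      a <- sample.int(s$n_sites, half)
      inc[a, 2 * k - 1] <- 1
      inc[setdiff(seq_len(s$n_sites), a), 2 * k] <- 1
    }
    extra <- seq(2 * s$n_pairs + 1, length.out = s$n_taxa - 2 * s$n_pairs)
    for (j in extra)
      inc[sample.int(s$n_sites, half), j] <- 1
  } else {
    # aggregation: pair members are co-placed on identical site sets, the
    # strongest pairwise attraction expressible in an incidence matrix.
    # Note that margin-preserving C-score nulls largely absorb this signal
    # (total pairwise overlap is fixed by site richness); see the vignette.
    sizes <- sample(seq(ceiling(s$n_sites / 4), floor(3 * s$n_sites / 4)),
                    s$n_pairs, replace = TRUE)
    for (k in seq_len(s$n_pairs)) {
      a <- sample.int(s$n_sites, sizes[k])
      inc[a, 2 * k - 1] <- 1
      inc[a, 2 * k] <- 1
    }
    extra <- seq(2 * s$n_pairs + 1, length.out = s$n_taxa - 2 * s$n_pairs)
    for (j in extra)
      inc[sample.int(s$n_sites, half), j] <- 1
  }
  inc
}

# 1 individual per presence, remainder multinomial with log-series-like
# taxon weights; total per occupied sample = target_total.
abundances_from_incidence <- function(inc, target_total = 100) {
  n_taxa <- ncol(inc)
  ranks <- sample.int(n_taxa)
  theta <- 0.85
  w <- theta ^ ranks / ranks          # log-series term x^k / k
  counts <- inc
  for (i in seq_len(nrow(inc))) {
    present <- which(inc[i, ] == 1)
    k <- length(present)
    if (k == 0L || k >= target_total) next
    extra <- stats::rmultinom(1, target_total - k, prob = w[present])[, 1]
    counts[i, present] <- 1 + extra
  }
  counts
}

synthetic_community <- function(counts, s) {
  n_sites <- nrow(counts)
  n_taxa <- ncol(counts)
  sample_meta <- data.frame(
    sample_id = sprintf("site%02d", seq_len(n_sites)),
    site = sprintf("site%02d", seq_len(n_sites)),
    land_cover = "synthetic", year = 1L, replicate = 1L,
    longitude = 120 + 0.1 * seq_len(n_sites),
    latitude = 40 + 0.1 * seq_len(n_sites),
    stringsAsFactors = FALSE)
  genus_meta <- data.frame(
    genus_id = sprintf("genus%02d", seq_len(n_taxa)),
    trophic_group = rep(trophic_groups(), length.out = n_taxa),
    stringsAsFactors = FALSE)
  community_table(counts, sample_meta, genus_meta)
}

# Site frame of the emulated survey: four stations spanning a ~10 degree
# latitude gradient, with mean annual temperature and precipitation.
study_sites <- function() {
  data.frame(
    site = c("Heihe", "Harbin", "Lishu", "Shenyang"),
    latitude = c(50.25, 45.6667, 43.35, 40.8),
    longitude = c(127.45, 126.5833, 124.6167, 123.55),
    mat = c(2.0, 5.5, 5.8, 7.9),
    map = c(510, 500, 576, 700),
    stringsAsFactors = FALSE)
}

#' Emulate the full survey design
#'
#' Generates a synthetic soil nematode survey with the study frame of the
#' emulated field campaign: 4 sites spanning a north-south latitude gradient
#' x 3 land covers x 3 replicate plots x 2 sampling years = 72 samples, with
#' at most 100 identified individuals per sample, a genus pool covering the
#' four trophic groups, and environmental variables (SM, ST, pH, STC, STN,
#' STP) that track latitude (via each site's mean annual temperature and
#' precipitation) plus within-site noise. Genus occupancy follows Gaussian
#' niches along the latitude gradient with land-cover-specific offsets, so
#' communities are spatially and environmentally structured.
#'
#' @param seed Integer seed.
#' @param n_taxa Genus pool size (default 32).
#' @param niche_sd Niche breadth in degrees latitude (default 3).
#' @param env_noise_sd Within-site environmental noise (default 0.5 SD
#'   units per variable).
#' @return List with `community` (a 72-sample `community_table`) and `env`
#'   (data frame of per-sample environmental variables).
#' @export
generate_study_design <- function(seed = 1L, n_taxa = 32, niche_sd = 3,
                                  env_noise_sd = 0.5) {
  set.seed(seed)
  sites <- study_sites()
  design <- expand.grid(year = c(2019L, 2021L), replicate = 1:3,
                        land_cover = land_covers(), site = sites$site,
                        stringsAsFactors = FALSE)
  design <- design[, c("site", "land_cover", "replicate", "year")]
  n <- nrow(design)                   # 4 * 3 * 3 * 2 = 72
  si <- match(design$site, sites$site)
  design$sample_id <- sprintf("%s_%s_r%d_%d", design$site,
                              substr(design$land_cover, 1, 2),
                              design$replicate, design$year)
  # replicate plots jitter around the station coordinates (~100 m)
  design$longitude <- sites$longitude[si] + stats::rnorm(n, 0, 0.002)
  design$latitude <- sites$latitude[si] + stats::rnorm(n, 0, 0.002)

  # genus pool with trophic groups
  genus_meta <- data.frame(
    genus_id = sprintf("genus%02d", seq_len(n_taxa)),
    trophic_group = rep(trophic_groups(), length.out = n_taxa),
    stringsAsFactors = FALSE)

  # Gaussian niches along latitude; land cover shifts the effective position
  centers <- stats::runif(n_taxa, min(sites$latitude) - 1,
                          max(sites$latitude) + 1)
  widths <- stats::runif(n_taxa, 0.3, 0.8) * niche_sd
  cover_shift <- stats::setNames(c(0, 0.8, -0.8), land_covers())
  # each plot also sits at its own microhabitat position on the suitability
  # axis (in latitude-equivalent units), so communities are structured
  # within sites, not only across them
  pos <- design$latitude + cover_shift[design$land_cover] +
    stats::rnorm(n, 0, 2.0)
  prob <- vapply(seq_len(n_taxa), function(j)
    0.92 * exp(-(pos - centers[j])^2 / (2 * widths[j]^2)), numeric(n))
  inc <- matrix(stats::rbinom(length(prob), 1, prob), n, n_taxa)
  empty <- rowSums(inc) == 0
  if (any(empty))
    for (i in which(empty)) inc[i, which.max(prob[i, ])] <- 1

  counts <- abundances_from_incidence(inc, target_total = 100)
  # identification stops at 100 individuals; a few samples fall short
  short <- stats::rbinom(n, 1, 0.15) * stats::rbinom(n, 8, 0.5)
  for (i in seq_len(n)) {
    over <- sum(counts[i, ]) - (100 - short[i])
    while (over > 0) {                 # trim from the most abundant genus
      j <- which.max(counts[i, ])
      take <- min(over, counts[i, j] - 1)
      if (take <= 0) break
      counts[i, j] <- counts[i, j] - take
      over <- over - take
    }
  }

  community <- community_table(counts, design, genus_meta)

  # environmental variables: latitude-linked means plus within-site noise
  env <- data.frame(
    sample_id = design$sample_id,
    SM = sites$map[si] / 25 + cover_shift[design$land_cover] +
      stats::rnorm(n, 0, 2 * env_noise_sd),
    ST = sites$mat[si] + 12 + 1.5 * cover_shift[design$land_cover] +
      stats::rnorm(n, 0, 1.5 * env_noise_sd),
    pH = 7.8 - 0.05 * (design$latitude - 40) +
      stats::rnorm(n, 0, 0.3 * env_noise_sd),
    STC = 8 + 1.1 * (design$latitude - 40) +
      stats::rnorm(n, 0, 2 * env_noise_sd),
    STN = 0.8 + 0.09 * (design$latitude - 40) +
      stats::rnorm(n, 0, 0.2 * env_noise_sd),
    STP = 0.55 + 0.02 * (design$latitude - 40) +
      stats::rnorm(n, 0, 0.1 * env_noise_sd),
    stringsAsFactors = FALSE)

  list(community = community, env = env)
}
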