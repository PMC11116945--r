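# Brute-force oracles, written independently of the package internals:
# explicit loops over every pair, no shared helpers.

bf_c_score <- function(m) {
  p <- ncol(m)
  total <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ri <- sum(m[, i]); rj <- sum(m[, j])
      s <- sum(m[, i] == 1 & m[, j] == 1)
      total <- total + (ri - s) * (rj - s)
    }
  }
  total / (p * (p - 1) / 2)
}

bf_embedded <- function(m, both_axes = TRUE) {
  count_gaps <- function(mm) {
    g <- 0
    for (j in seq_len(ncol(mm))) {
      ones <- which(mm[, j] == 1)
      if (length(ones) >= 2) {
        for (r in (min(ones)):(max(ones))) {
          if (mm[r, j] == 0) g <- g + 1
        }
      }
    }
    g
  }
  count_gaps(m) + if (both_axes) count_gaps(t(m)) else 0
}

bf_fill <- function(m) {
  for (j in seq_len(ncol(m))) {
    ones <- which(m[, j] == 1)
    if (length(ones) >= 2) m[min(ones):max(ones), j] <- 1
  }
  m
}

# opposing presence-absence pairs over every (site pair, genus pair)
bf_replacements <- function(m, fill = TRUE) {
  if (fill) m <- bf_fill(m)
  n <- nrow(m); p <- ncol(m)
  total <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      for (i in seq_len(p - 1)) {
        for (j in (i + 1):p) {
          opp1 <- m[a, i] == 1 && m[b, i] == 0 && m[b, j] == 1 && m[a, j] == 0
          opp2 <- m[b, i] == 1 && m[a, i] == 0 && m[a, j] == 1 && m[b, j] == 0
          if (opp1 || opp2) total <- total + 1
        }
      }
    }
  }
  total
}

# random binary matrix with no all-zero row or column
random_incidence <- function(nr, nc, fill = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# small pruned community table around a given count matrix
toy_community <- function(counts) {
  nr <- nrow(counts); nc <- ncol(counts)
  community_table(
    counts,
    data.frame(sample_id = paste0("s", seq_len(nr)), site = "A",
               land_cover = "farmland", year = 1, replicate = seq_len(nr),
               longitude = seq_len(nr), latitude = seq_len(nr)),
    data.frame(genus_id = paste0("g", seq_len(nc)),
               trophic_group = rep(c("PF", "BF", "FF", "OP"),
                                   length.out = nc)))
}
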