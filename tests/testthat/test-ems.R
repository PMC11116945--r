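test_that("embedded absences count gaps inside ranges", {
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  expect_equal(embedded_absences(m, mode = "columns_only"), 1)
  expect_equal(embedded_absences(m, mode = "both_axes"), 2)
  expect_equal(embedded_absences(matrix(1, 4, 4)), 0)

  banded <- matrix(0, 5, 5)
  for (i in 1:5) banded[i, max(1, i - 1):min(5, i + 1)] <- 1
  expect_equal(embedded_absences(banded), 0)
})

test_that("replacements count opposing presence-absence pairs", {
  # perfectly nested: no opposing pairs
  nested <- matrix(0, 4, 4)
  for (j in 1:4) nested[seq_len(5 - j), j] <- 1
  expect_equal(replacements(nested), 0)
  # single checkerboard: one opposing pair
  expect_equal(replacements(matrix(c(1, 0, 0, 1), 2)), 1)
  # partial overlap: one replacement between the end sites
  m <- cbind(c(1, 1, 0), c(0, 1, 1))
  expect_equal(replacements(m), 1)
})

test_that("count statistics equal brute-force enumeration", {
  set.seed(14)
  for (k in 1:40) {
    nr <- sample(3:6, 1); nc <- sample(3:6, 1)
    m <- matrix(rbinom(nr * nc, 1, runif(1, 0.3, 0.7)), nr, nc)
    expect_equal(embedded_absences(m, "both_axes"), bf_embedded(m, TRUE))
    expect_equal(embedded_absences(m, "columns_only"), bf_embedded(m, FALSE))
    expect_equal(replacements(m), bf_replacements(m))
    expect_equal(replacements(m, fill = FALSE), bf_replacements(m, fill = FALSE))
    expect_equal(fill_ranges(m), bf_fill(m))
  }
})

test_that("element counts are invariant to reversing the ordination axis", {
  set.seed(15)
  for (k in 1:10) {
    m <- random_incidence(6, 6, 0.5)
    rev_m <- m[6:1, 6:1]
    expect_equal(embedded_absences(m), embedded_absences(rev_m))
    expect_equal(replacements(m), replacements(rev_m))
    expect_equal(morisita_boundary(m)$morisita_i,
                 morisita_boundary(rev_m)$morisita_i)
  }
})

test_that("Morisita boundary index hits its closed-form landmarks", {
  # both genera confined to one of four sites: all 4 boundaries together
  m1 <- rbind(c(1, 1), c(0, 0), c(0, 0), c(0, 0))
  b1 <- morisita_boundary(m1)
  expect_equal(b1$morisita_i, 4)          # = n, maximal clumping
  expect_equal(b1$df, 3)

  # one boundary per site: no clumping at all
  m2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(morisita_boundary(m2)$morisita_i, 0)

  # two sites sharing half of many boundaries: I approaches 1 from below
  m3 <- cbind(matrix(rep(c(1, 0, 0, 0), 10), 4),
              matrix(rep(c(0, 0, 0, 1), 10), 4))
  f <- morisita_boundary(m3)$boundary_counts
  expect_equal(f, c(20, 0, 0, 20))
  i3 <- morisita_boundary(m3)$morisita_i
  expect_equal(i3, 4 * 2 * 20 * 19 / (40 * 39))
  expect_lt(i3, 2)
  expect_error(morisita_boundary(matrix(1, 1, 3)),
               class = "nemastruct_degenerate")
})

test_that("the decision tree reproduces published structure labels", {
  ref <- reference_ems_stats()
  # the four landmark rows spanning the tree's branches
  pick <- function(sc, lc, st) ref[ref$scale == sc & ref$land_cover == lc &
                                     (is.na(ref$site) | ref$site == st), ]
  expect_equal(classify_reference_row(pick("local", "farmland", "Heihe")),
               "Quasi-Clementsian")
  expect_equal(classify_reference_row(pick("local", "woodland", "Harbin")),
               "Clementsian")
  expect_equal(classify_reference_row(pick("local", "woodland", "Heihe")),
               "Quasi-nested (clumped loss)")
  expect_equal(classify_reference_row(pick("local", "woodland", "Lishu")),
               "Gleasonian")

  # non-significant coherence short-circuits to Random
  coh <- list(obs = 10, null_mean = 12, p = 0.50)
  tur <- list(obs = 100, null_mean = 50, p = 0.001)
  bnd <- list(morisita_i = 2, p = 0.001)
  expect_equal(classify_structure(coh, tur, bnd), "Random")
  # more absences than expected: checkerboard
  coh2 <- list(obs = 30, null_mean = 12, p = 0.001)
  expect_equal(classify_structure(coh2, tur, bnd), "Checkerboard")
  # evenly spaced branch and its quasi variant
  bnd2 <- list(morisita_i = 0.4, p = 0.01)
  coh3 <- list(obs = 5, null_mean = 12, p = 0.001)
  expect_equal(classify_structure(coh3, tur, bnd2), "Evenly spaced")
  expect_equal(classify_structure(coh3, list(obs = 100, null_mean = 50,
                                             p = 0.4), bnd2),
               "Quasi-evenly spaced")
})

test_that("the pipeline recovers seeded nested and random structures", {
  nest <- generate_metacommunity(synthetic_scenario("nested", seed = 71))
  res <- ems_pipeline(nest, n_sims = 100, seed = 5)
  expect_match(res$label, "[Nn]ested")

  rnd <- generate_metacommunity(synthetic_scenario("random", seed = 72))
  res2 <- suppressWarnings(ems_pipeline(rnd, n_sims = 100, seed = 5))
  expect_equal(res2$label, "Random")

  one_genus <- toy_community(matrix(c(1, 2, 3), 3, 1))
  expect_error(ems_pipeline(one_genus, n_sims = 10, seed = 1),
               class = "nemastruct_degenerate")
})

test_that("EMS reports carry the full provenance row per unit", {
  tab <- generate_metacommunity(synthetic_scenario("clementsian", seed = 3))
  res <- ems_pipeline(tab, n_sims = 60, seed = 9)
  rep_tab <- ems_report(list(unitA = res))
  expect_equal(nrow(rep_tab), 1)
  expect_equal(rep_tab$seed, 9)
  expect_equal(rep_tab$n_sims, 60)
  expect_true(all(c("Abs", "coh_p", "Rep", "tur_p", "I", "structure")
                  %in% names(rep_tab)))
  # z is consistent with the stored null moments
  expect_equal(rep_tab$coh_z,
               (rep_tab$Abs - rep_tab$coh_mean) / rep_tab$coh_sd)
})
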