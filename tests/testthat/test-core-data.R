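test_that("incidence conversion binarizes, prunes and records drops", {
  inc <- to_incidence(matrix(c(3, 1, 0, 2), 2))
  expect_equal(unclass(inc)[, ], matrix(c(1, 1, 0, 1), 2),
               ignore_attr = TRUE)

  # all-zero column dropped and recorded
  inc2 <- to_incidence(matrix(c(2, 5, 0, 0), 2,
                              dimnames = list(c("a", "b"), c("g1", "g2"))))
  expect_equal(dim(inc2), c(2L, 1L))
  expect_equal(attr(inc2, "dropped_cols"), "g2")

  # threshold shifts the presence cut
  inc3 <- to_incidence(matrix(c(3, 1, 0, 2), 2), threshold = 2)
  expect_equal(sum(inc3), 2)

  expect_error(to_incidence(matrix(0, 2, 2)),
               class = "nemastruct_degenerate")
})

test_that("incidence conversion is idempotent on binary input", {
  set.seed(11)
  for (k in 1:10) {
    m <- random_incidence(5, 6, 0.4)
    once <- to_incidence(m)
    twice <- to_incidence(once)
    expect_equal(unclass(once)[, ], unclass(twice)[, ], ignore_attr = TRUE)
  }
})

test_that("design subsets have the expected sample counts", {
  tab <- generate_study_design(seed = 42)$community
  reg <- subset_community(tab, "farmland", "regional")
  expect_equal(nrow(reg$counts), 24)   # 4 sites x 3 reps x 2 years
  loc <- subset_community(tab, "farmland", "local", site = "Heihe")
  expect_equal(nrow(loc$counts), 6)    # 3 reps x 2 years
  expect_equal(unique(loc$sample_meta$site), "Heihe")

  expect_error(subset_community(tab, "wetland", "regional"),
               "unknown land cover")
  expect_error(subset_community(tab, "farmland", "local"),
               "site is required")
  expect_error(subset_community(tab, "farmland", "local", site = "Paris"),
               "unknown site")
})

test_that("trophic subsets partition the genus set", {
  tab <- generate_study_design(seed = 7)$community
  parts <- lapply(c("PF", "BF", "FF", "OP"),
                  function(g) subset_trophic(tab, g)$genus_meta$genus_id)
  expect_equal(sort(unlist(parts)), sort(tab$genus_meta$genus_id))
  expect_equal(anyDuplicated(unlist(parts)), 0L)
  # sample rows unchanged
  expect_equal(rownames(subset_trophic(tab, "BF")$counts),
               rownames(tab$counts))

  expect_error(subset_trophic(tab, "XX"), "unknown trophic group")
  no_op <- toy_community(matrix(1, 2, 2))  # only PF and BF columns
  expect_error(subset_trophic(no_op, "FF"),
               class = "nemastruct_degenerate")
})

test_that("subsetting commutes with incidence conversion up to pruning", {
  tab <- generate_study_design(seed = 3)$community
  sub <- subset_community(tab, "grassland", "local", site = "Lishu",
                          drop_empty_genera = FALSE)
  inc_sub <- to_incidence(sub)
  inc_full <- to_incidence(tab)
  rows <- intersect(rownames(inc_sub), rownames(inc_full))
  cols <- intersect(colnames(inc_sub), colnames(inc_full))
  expect_equal(unclass(inc_sub)[rows, cols],
               unclass(inc_full)[rows, cols])
})

test_that("community table construction validates inputs", {
  counts <- matrix(1, 2, 2)
  sm <- data.frame(sample_id = c("a", "a"), site = "A",
                   land_cover = "farmland", year = 1, replicate = 1:2,
                   longitude = 0, latitude = 0)
  gm <- data.frame(genus_id = c("g1", "g2"), trophic_group = c("PF", "BF"))
  expect_error(community_table(counts, sm, gm), "duplicate sample_id")
  sm$sample_id <- c("a", "b")
  expect_error(community_table(matrix(-1, 2, 2), sm, gm), "invalid count")
  expect_error(community_table(counts, sm, gm[1, , drop = FALSE]),
               "columns")
  gm$trophic_group <- c("PF", "herbivore")
  expect_error(community_table(counts, sm, gm), "unknown trophic group")
})

test_that("env alignment reports missing samples by name", {
  tab <- toy_community(matrix(1, 3, 2))
  env <- data.frame(sample_id = c("s1", "s3"), SM = 1:2, pH = c(6, 7))
  expect_error(align_env(env, tab), "s2")
  env_full <- data.frame(sample_id = c("s3", "s1", "s2"), SM = 1:3)
  aligned <- align_env(env_full, tab)
  expect_equal(aligned$sample_id, c("s1", "s2", "s3"))
})
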