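test_that("row-fixed randomization preserves row sums and is seeded", {
  set.seed(2)
  for (k in 1:8) {
    m <- random_incidence(6, 8, 0.5)
    r1 <- randomize_row_fixed(m, seed = 100 + k)
    expect_equal(rowSums(r1), rowSums(m))
    expect_true(all(r1 %in% c(0, 1)))
    r2 <- randomize_row_fixed(m, seed = 100 + k)
    expect_identical(r1, r2)
  }
})

test_that("row-fixed column placement follows observed column totals", {
  set.seed(4)
  m <- random_incidence(6, 8, 0.45)
  n_draws <- 10000
  acc <- numeric(ncol(m))
  for (i in seq_len(n_draws))
    acc <- acc + colSums(randomize_row_fixed(m))
  # without-replacement sampling spreads mass: compare against an empirical
  # Monte-Carlo band rather than the exact (intractable) expectation is not
  # enough here, so check the rank agreement and proportional band loosely
  p_hat <- acc / sum(acc)
  p_obs <- colSums(m) / sum(m)
  se <- sqrt(p_obs * (1 - p_obs) / (n_draws * nrow(m)))
  expect_true(all(abs(p_hat - p_obs) < 3 * se + 0.02))
})

test_that("checkerboard swaps flip and preserve both margins", {
  m <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(swap_fixed_fixed(m, 1, seed = 1),
               matrix(c(0, 1, 1, 0), 2))
  # no checkerboard submatrix: unchanged no matter how many attempts
  frozen <- matrix(c(1, 1, 1, 0), 2)
  expect_equal(swap_fixed_fixed(frozen, 500, seed = 3), frozen)

  set.seed(6)
  for (k in 1:6) {
    m <- random_incidence(7, 9, 0.4)
    out <- swap_fixed_fixed(m, 5000, seed = k)
    expect_equal(rowSums(out), rowSums(m))
    expect_equal(colSums(out), colSums(m))
  }
})

test_that("null distributions flag conserved statistics as degenerate", {
  m <- random_incidence(5, 6, 0.5)
  nd <- null_distribution(sum, m, method = "row_fixed", n_sims = 20,
                          seed = 2)
  expect_true(nd$degenerate)
  expect_equal(nd$sd, 0)
  expect_error(z_and_p(10, nd), "degenerate null")

  # 2x2 checkerboard: the margin class has exactly two states, both single
  # checkerboards with one unit per genus pair, so the statistic is frozen
  cb <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(c_score(cb), 1)                       # (1-0)(1-0) / 1 pair
  expect_equal(c_score(matrix(c(0, 1, 1, 0), 2)), 1) # the only other state
  nd2 <- null_distribution(c_score, cb, method = "fixed_fixed",
                           n_sims = 30, seed = 1)
  expect_true(all(nd2$values == 1))
  expect_true(nd2$degenerate)

  expect_error(null_distribution(sum, m, n_sims = 1), "at least 2")
})

test_that("null distribution values are reproducible from the seed", {
  m <- random_incidence(6, 6, 0.5)
  a <- null_distribution(c_score, m, method = "fixed_fixed", n_sims = 25,
                         seed = 7)
  b <- null_distribution(c_score, m, method = "fixed_fixed", n_sims = 25,
                         seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(a$mean, mean(a$values))
  expect_equal(a$sd, sd(a$values))
})

test_that("z-score arithmetic matches published null-model summaries", {
  # turnover of the northernmost farmland unit
  expect_equal(round(z_and_p(639, mean = 507.69, sd = 75.78)$z, 2), 1.73)
  # coherence of the southernmost grassland unit
  expect_equal(round(z_and_p(65, mean = 278.34, sd = 8.24)$z, 2), -25.89)

  zp <- z_and_p(5, mean = 5, sd = 2)
  expect_equal(zp$z, 0)
  expect_equal(zp$p, 1)
  expect_error(z_and_p(1, mean = 1, sd = 0), "degenerate")
})

test_that("z and p are antisymmetric about the null mean", {
  set.seed(8)
  for (k in 1:10) {
    mu <- rnorm(1, 50, 10); s <- runif(1, 1, 5); obs <- rnorm(1, mu, 3 * s)
    a <- z_and_p(obs, mean = mu, sd = s)
    b <- z_and_p(2 * mu - obs, mean = mu, sd = s)
    expect_equal(a$z, -b$z)
    expect_equal(a$p, b$p)
  }
})

test_that("derived seeds separate simulation streams", {
  seeds <- vapply(1:500, function(i) derive_seed(123, i), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_false(derive_seed(1, 5) == derive_seed(2, 5))
})
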