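# independent oracle: first non-trivial correspondence axis via
# eigen-decomposition of the symmetric standardized cross-product
oracle_row_scores <- function(m) {
  p <- m / sum(m)
  r <- rowSums(p); cc <- colSums(p)
  s <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  e <- eigen(s %*% t(s), symmetric = TRUE)
  v <- e$vectors[, 1] / sqrt(r)
  v / sqrt(sum(r * v^2))   # unit weighted norm, matching CA standard coords
}

same_up_to_reversal <- function(a, b) {
  identical(a, b) || identical(a, rev(b))
}

test_that("banded matrices are recovered in band order", {
  m <- matrix(0, 6, 6)
  for (i in 1:6) m[i, max(1, i - 1):min(6, i + 1)] <- 1
  ord <- reciprocal_averaging(to_incidence(m))
  expect_true(same_up_to_reversal(ord$row_order, 1:6))
  expect_true(same_up_to_reversal(ord$col_order, 1:6))
  # a banded matrix in band order has contiguous ranges: zero gaps
  expect_equal(embedded_absences(ord$ordered_matrix), 0)
})

test_that("scores match the eigen-decomposition oracle on random matrices", {
  set.seed(21)
  for (k in 1:20) {
    m <- random_incidence(5, 5, 0.5)
    ord <- tryCatch(reciprocal_averaging(m),
                    warning = function(w) NULL,   # disconnected draw
                    error = function(e) NULL)     # flat-gradient draw
    if (is.null(ord)) next
    oracle <- oracle_row_scores(m)
    flip <- sign(sum(oracle * ord$site_scores))
    expect_equal(unname(ord$site_scores), flip * oracle, tolerance = 1e-6,
                 info = paste("seeded case", k))
  }
})

test_that("iterative averaging agrees with the direct axis", {
  set.seed(33)
  for (k in 1:10) {
    m <- random_incidence(6, 7, 0.45)
    d <- tryCatch(reciprocal_averaging(m, method = "direct"),
                  warning = function(w) NULL, error = function(e) NULL)
    if (is.null(d)) next
    it <- suppressWarnings(reciprocal_averaging(m, method = "iterative"))
    flip <- sign(sum(d$site_scores * it$site_scores))
    expect_equal(unname(it$site_scores), flip * unname(d$site_scores),
                 tolerance = 1e-6)
    expect_equal(unname(it$genus_scores), flip * unname(d$genus_scores),
                 tolerance = 1e-6)
  }
})

test_that("ordering is invariant to shuffling the input rows", {
  set.seed(5)
  m <- random_incidence(8, 6, 0.5)
  rownames(m) <- paste0("r", 1:8); colnames(m) <- paste0("c", 1:6)
  ord1 <- reciprocal_averaging(m)
  perm <- sample(8)
  ord2 <- reciprocal_averaging(m[perm, ])
  expect_equal(unclass(ord1$ordered_matrix)[, ],
               unclass(ord2$ordered_matrix)[, ], ignore_attr = TRUE)
})

test_that("sign convention orients the first axis reproducibly", {
  set.seed(9)
  m <- random_incidence(7, 5, 0.5)
  ord <- reciprocal_averaging(m)
  expect_lte(ord$site_scores[1], ord$site_scores[length(ord$site_scores)])
})

test_that("degenerate and disconnected matrices are handled", {
  expect_error(reciprocal_averaging(matrix(1, 1, 4)),
               class = "nemastruct_degenerate")
  expect_error(reciprocal_averaging(matrix(1, 4, 4)),
               class = "nemastruct_degenerate")  # no gradient
  expect_error(reciprocal_averaging(matrix(c(1, 0, 1, 1), 2, 2) * 2),
               "binary")

  blockm <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 2)),
                  cbind(matrix(0, 2, 3), matrix(1, 2, 2)))
  blockm[1, 2] <- 0; blockm[5, 5] <- 0  # avoid flat within-block scores
  expect_warning(ordd <- reciprocal_averaging(blockm), "disconnected")
  expect_true(ordd$disconnected)
  # larger component (rows 1-3) comes first
  expect_true(all(ordd$row_order[1:3] %in% 1:3))
})
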