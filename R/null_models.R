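#' Row-fixed randomization of an incidence matrix
#'
#' Each output row keeps the input row's presence count; within a row the
#' presences are placed by sampling columns without replacement with
#' probabilities proportional to the observed column totals. This is the
#' classic "r1" null of metacommunity analysis: site richness is fixed,
#' genus incidence is proportional to observed prevalence.
#'
#' @param m Binary incidence matrix (pruned).
#' @param seed Optional integer seed for this single draw.
#' @return A binary matrix with identical row sums and dimnames.
#' @export
randomize_row_fixed <- function(m, seed = NULL) {
  m <- unclass_incidence(m)
  if (!is_binary_matrix(m)) stop("incidence matrix must be binary")
  if (!is.null(seed)) set.seed(seed)
  nc <- ncol(m)
  rs <- rowSums(m)
  if (any(rs > nc))
    stop("row sum exceeds number of columns; randomization impossible")
  w <- colSums(m)
  out <- matrix(0, nrow(m), nc, dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    cols <- sample.int(nc, rs[i], replace = FALSE, prob = w)
    out[i, cols] <- 1
  }
  out
}

#' Fixed-fixed sequential-swap randomization
#'
#' Performs `n_swaps` attempted 2x2 checkerboard swaps on random row and
#' column pairs. Every successful swap flips a checkerboard submatrix, so
#' both row and column sums are preserved exactly at every step; attempts on
#' non-checkerboard submatrices leave the matrix unchanged.
#'
#' @param m Binary incidence matrix (pruned).
#' @param n_swaps Number of attempted swaps.
#' @param seed Optional integer seed.
#' @return A binary matrix with the input's row and column sums.
#' @export
swap_fixed_fixed <- function(m, n_swaps, seed = NULL) {
  dm <- dimnames(m)
  m <- unclass_incidence(m)
  if (!is_binary_matrix(m)) stop("incidence matrix must be binary")
  if (!is.null(seed)) set.seed(seed)
  im <- m
  storage.mode(im) <- "integer"
  out <- cpp_swap_chain(im, as.numeric(n_swaps))
  out <- matrix(as.numeric(out), nrow(m), ncol(m), dimnames = dm)
  out
}

#' Simulate a null distribution of a matrix statistic
#'
#' Applies `stat` to `n_sims` randomizations of `m`. Under `row_fixed` the
#' randomizations are independent draws, each from its own derived seed.
#' Under `fixed_fixed` they are states of a sequential-swap Markov chain: a
#' burn-in of `10 * fill` attempted swaps precedes sampling and `fill`
#' attempted swaps separate consecutive samples (fill = number of presences),
#' so the sampled matrices are approximately independent.
#'
#' @param stat Function taking a binary matrix and returning one number.
#' @param m Binary incidence matrix.
#' @param method `"row_fixed"` or `"fixed_fixed"`.
#' @param n_sims Number of simulated values (at least 2).
#' @param seed Integer seed governing the whole simulation.
#' @param burn_in,thin Overrides for the fixed-fixed chain schedule.
#' @return An object of class `null_distribution`: `values`, `mean`, `sd`,
#'   `method`, `n_sims`, `seed`, and a `degenerate` flag set when the
#'   simulated statistic has zero spread.
#' @export
null_distribution <- function(stat, m, method = c("row_fixed", "fixed_fixed"),
                              n_sims = 1000, seed = 1L,
                              burn_in = NULL, thin = NULL) {
  method <- match.arg(method)
  stopifnot(is.function(stat))
  if (!is.numeric(n_sims) || n_sims < 2)
    stop("n_sims must be at least 2")
  m <- unclass_incidence(m)
  values <- numeric(n_sims)
  if (method == "row_fixed") {
    for (i in seq_len(n_sims))
      values[i] <- stat(randomize_row_fixed(m, seed = derive_seed(seed, i)))
  } else {
    fill <- sum(m)
    burn_in <- burn_in %||% (10 * fill)
    thin <- thin %||% fill
    set.seed(derive_seed(seed, 0L))
    im <- m
    storage.mode(im) <- "integer"
    state <- cpp_swap_chain(im, as.numeric(burn_in))
    for (i in seq_len(n_sims)) {
      state <- cpp_swap_chain(state, as.numeric(thin))
      values[i] <- stat(matrix(as.numeric(state), nrow(m), ncol(m)))
    }
  }
  null_dist(values, method, seed)
}

null_dist <- function(values, method, seed) {
  s <- stats::sd(values)
  structure(list(values = values, mean = mean(values), sd = s,
                 method = method, n_sims = length(values), seed = seed,
                 degenerate = isTRUE(s == 0)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution (", x$method, ", n_sims = ", x$n_sims, ")\n",
      sep = "")
  cat("  mean = ", format(x$mean, digits = 6), ", sd = ",
      format(x$sd, digits = 6), if (x$degenerate) "  [degenerate]", "\n",
      sep = "")
  invisible(x)
}

#' Z-score and two-tailed normal p-value against a null distribution
#'
#' `z = (obs - mean) / sd` with the two-tailed tail probability of |z| under
#' the standard normal. The null can be given as a [null_distribution()]
#' object or as printed summary moments (`mean`, `sd`), which makes the
#' arithmetic reusable on published tables.
#'
#' @param obs Observed statistic.
#' @param null Optional `null_distribution`.
#' @param mean,sd Null moments, used when `null` is absent.
#' @return List with elements `z` and `p`.
#' @export
z_and_p <- function(obs, null = NULL, mean = NULL, sd = NULL) {
  if (!is.null(null)) {
    stopifnot(inherits(null, "null_distribution"))
    mean <- null$mean
    sd <- null$sd
  }
  stopifnot(is.numeric(obs), is.numeric(mean), is.numeric(sd))
  if (sd <= 0) stop("degenerate null: sd is zero")
  z <- (obs - mean) / sd
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Empirical two-tailed p-value from simulated values
#'
#' Alternative to the normal approximation: the proportion of simulated
#' values at least as extreme as the observation (about the null mean), with
#' the +1 correction.
#'
#' @param obs Observed statistic.
#' @param null A `null_distribution`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  dev <- abs(obs - null$mean)
  (1 + sum(abs(null$values - null$mean) >= dev)) / (1 + null$n_sims)
}
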