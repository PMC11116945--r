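#' @useDynLib nemastruct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dist pnorm pchisq sd rnorm runif rbinom quantile
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific seed from a global seed
#'
#' Counter-based fan-out: each (seed, index) pair maps to a distinct 31-bit
#' seed so independent randomizations are reproducible and order-independent.
#'
#' @param seed Integer global seed.
#' @param index Nonnegative integer counter.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  # Weyl-style multiplicative mix, kept inside 31 bits for R's set.seed()
  h <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(h %% 2147483646) + 1L
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("nemastruct_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

as_count_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}
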