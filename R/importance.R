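#' Permutation importance of environmental and spatial variables
#'
#' Fits a random-forest regression of the ordination site scores on the
#' environmental and spatial variables and reports each variable's
#' permutation importance (mean % increase in out-of-bag MSE when the
#' variable is permuted). Significance comes from a response-permutation
#' null: the forest is refit `n_perms` times with the response shuffled and
#' each variable's observed importance is compared with its own null
#' importances, `p = (1 + #[null >= obs]) / (1 + n_perms)`.
#'
#' @param site_scores Numeric response, one score per sample (first
#'   ordination axis; see [reciprocal_averaging()]).
#' @param variables Data frame of predictors (typically SM, ST, pH, STC,
#'   STN, STP, longitude, latitude); complete cases required.
#' @param n_trees Trees per forest (default 500).
#' @param n_perms Response permutations for the null (default 100).
#' @param seed Integer seed.
#' @return List of class `importance_result` with a data frame `table`
#'   (variable, importance, p, signif, rank; sorted by importance) and the
#'   model settings.
#' @export
importance_analysis <- function(site_scores, variables, n_trees = 500,
                                n_perms = 100, seed = 1L) {
  stopifnot(is.numeric(site_scores))
  variables <- as.data.frame(variables)
  variables <- variables[, setdiff(names(variables), "sample_id"),
                         drop = FALSE]
  if (nrow(variables) != length(site_scores))
    stop("site_scores and variables disagree in length")
  if (length(site_scores) < 8L)
    stop("importance analysis needs at least 8 observations")
  if (anyNA(variables)) stop("variables must be complete (no NA)")
  if (stats::sd(site_scores) == 0) stop("constant response: no gradient to explain")

  fit_importance <- function(y, sd) {
    set.seed(sd)
    fit <- randomForest::randomForest(x = variables, y = y,
                                      ntree = n_trees, importance = TRUE)
    randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  }
  obs <- fit_importance(site_scores, derive_seed(seed, 0L))
  null_imp <- matrix(NA_real_, n_perms, length(obs))
  for (i in seq_len(n_perms)) {
    set.seed(derive_seed(seed, 2L * i))
    y_perm <- sample(site_scores)
    null_imp[i, ] <- fit_importance(y_perm, derive_seed(seed, 2L * i + 1L))
  }
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(null_imp[, j] >= obs[j])) / (1 + n_perms), numeric(1))
  tab <- data.frame(variable = names(obs), importance = unname(obs),
                    p = p, signif = signif_code(p),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 settings = list(n_trees = n_trees, n_perms = n_perms,
                                 seed = seed, n_obs = length(site_scores))),
            class = "importance_result")
}

signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Permutation importance (", x$settings$n_trees, " trees, ",
      x$settings$n_perms, " response permutations)\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}
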