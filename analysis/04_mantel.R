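#!/usr/bin/env Rscript
# Step 4: Mantel tests of community dissimilarity against environmental and
# geographic distance.
#
# Bray-Curtis dissimilarity of the abundance tables is correlated (Spearman)
# with the Euclidean distance of the standardized soil variables and with
# the great-circle distance between plots, one-tailed with 9999 label
# permutations, for every analysis unit.

library(nemastruct)

io <- read_community("results/data/survey_counts.csv",
                     "results/data/survey_samples.csv",
                     "results/data/survey_genera.csv",
                     "results/data/survey_env.csv")
tab <- io$community
env <- io$env

units <- list()
for (lc in unique(tab$sample_meta$land_cover)) {
  for (st in unique(tab$sample_meta$site)) {
    sub <- subset_community(tab, lc, "local", site = st)
    units[[paste(st, lc, sep = "/")]] <-
      list(table = sub, env = align_env(env, sub))
  }
  sub <- subset_community(tab, lc, "regional")
  units[[paste("regional", lc, sep = "/")]] <-
    list(table = sub, env = align_env(env, sub))
}

report <- mantel_report(units, n_perm = 9999, seed = 20240604)
write.csv(report, "results/mantel_report.csv", row.names = FALSE)

cat("\nMantel report\n")
print(report[, c("unit", "env_r", "env_p", "spa_r", "spa_p")], digits = 3)
reg <- report[grepl("^regional/", report$unit), ]
cat("\nregional-scale significant correlations (p < .05): env ",
    sum(reg$env_p < 0.05), "/3, spatial ", sum(reg$spa_p < 0.05), "/3\n",
    sep = "")
cat("written to results/mantel_report.csv\n")
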