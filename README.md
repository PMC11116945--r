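# nemastruct

Metacommunity structure analysis for soil nematode communities (and other
site-by-taxon tables): elements of metacommunity structure (EMS) with the
full quasi-structure taxonomy, C-score/SES co-occurrence null models, Mantel
distance-decay tests, and permutation importance of ordination gradients —
plus a synthetic survey generator so the whole pipeline can be exercised,
calibrated and reproduced without field data.

## The problem

Soil nematodes are the most abundant soil metazoans and are surveyed as
genus-level count tables across sites, land covers and years. Community
ecologists ask which idealized metacommunity structure such a table
expresses — Clementsian (discrete communities responding jointly to a
gradient), Gleasonian (independent species responses), nested, evenly
spaced, checkerboard, or random — and which processes (environmental
heterogeneity, dispersal limitation, biological interactions) shape it at
local versus regional scales. `nemastruct` implements that analysis chain:

1. **EMS.** The presence–absence matrix is ordinated by reciprocal
   averaging (first correspondence-analysis axis). Three elements are then
   tested against null models: *coherence* (embedded absences `Abs` — zeros
   inside a genus' range on the ordered matrix), *turnover* (replacements
   `Rep` — opposing presence/absence pairs over all site and genus pairs on
   range-filled matrices), and *boundary clumping* (Morisita's index
   `I = n Σ f_i(f_i−1) / (F(F−1))` on the per-site counts of range
   boundaries, with a chi-squared dispersion test). A decision tree over
   the three tests yields one of the structure labels, with Quasi- variants
   when turnover is non-significant.
2. **Co-occurrence.** The C-score — the mean number of checkerboard units
   `(R_i − S)(R_j − S)` over all genus pairs — is compared with 10,000
   fixed-fixed (sequential-swap) null matrices; the standardized effect
   size `SES = (obs − mean_null)/sd_null` flags non-random segregation
   above 2, overall and within trophic groups (plant parasites,
   bacterivores, fungivores, omnivores–predators).
3. **Distance decay.** Bray–Curtis community dissimilarity is correlated
   (Spearman, permutation Mantel test) with Euclidean environmental
   distance and great-circle geographic distance.
4. **Gradient importance.** Ordination site scores are regressed on soil
   variables (SM, ST, pH, STC, STN, STP) and coordinates with a random
   forest; permutation importance is tested against a response-permutation
   null.

## Worked example

```r
library(nemastruct)

survey <- generate_study_design(seed = 1)   # 72-sample emulated survey
grass  <- subset_community(survey$community, "grassland", "regional")

ems_pipeline(grass, n_sims = 1000, seed = 1)
#> EMS analysis
#>   Coherence: Abs = 173, null 612.86 (SD 89.62), z = -4.91, p = 9.21e-07
#>   Turnover:  Rep = 13498, null 4730.27 (SD 2553.51), z = 3.43, p = 0.000596
#>   Boundary:  I = 1.52, chi2 = 56.00 (df 23), p = 0.000142
#>   Structure: Clementsian

cooccurrence_analysis(grass, n_sims = 10000, seed = 1)
#> Co-occurrence analysis
#>   C-score = 19.8367, null 18.1915 (SD 0.0889), SES = 18.50
#>   SES > 2: non-random segregation
```

Reading the numbers: the regional grassland community holds far fewer
embedded absences than its null expectation (significant positive
coherence), more replacements than expected (significant turnover), and
boundaries clump (`I` significantly above 1) — a Clementsian structure:
genera turn over along the latitude gradient in discrete groups. The
C-score sits 18.5 null standard deviations above the fixed-margin
expectation: genus pairs are segregated beyond what richness and
prevalence impose.

The distance-decay stage works the same way:

```r
dc <- bray_curtis(grass)
de <- euclidean_env(align_env(survey$env, grass)[, c("SM","ST","pH","STC","STN","STP")])
rownames(de) <- colnames(de) <- rownames(as.matrix(dc))
mantel_test(dc, de, n_perm = 9999, seed = 1)
#> Mantel test (spearman, greater): r = 0.428, p = 0.0001 (9999 permutations)
```

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
emulation; each is a thin narrative script over the package functions and
writes delimited reports under `results/`:

```sh
Rscript analysis/01_simulate.R      # emulated survey -> results/data/
Rscript analysis/02_ems.R           # EMS per unit    -> results/ems_report.csv
Rscript analysis/03_cooccurrence.R  # C-score/SES     -> results/cooccurrence_report.csv
Rscript analysis/04_mantel.R        # distance decay  -> results/mantel_report.csv
Rscript analysis/05_importance.R    # random forest   -> results/importance_report.csv
```

`run_all()` performs the same sweep programmatically (12 local + 3 regional
units), and `read_run_config()` accepts a YAML configuration.

## The methods vignette

`vignettes/metacommunity-structure.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, the
null-model algorithms (including why the fixed-fixed C-score detects
segregation but not aggregation), the synthetic generator's scope and
limits, and the package's numerical conventions.
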