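---
title: "Metacommunity structure analysis for soil nematode communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacommunity structure analysis for soil nematode communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nemastruct` implements the elements-of-metacommunity-structure (EMS)
analysis for site-by-genus community tables, together with the supporting
analyses that typically accompany it in soil-fauna studies: C-score/SES
co-occurrence tests, Mantel tests of distance decay, and a
permutation-importance regression of ordination site scores on
environmental and spatial variables. A synthetic-data module emulates a
multi-site, multi-land-cover nematode survey so that every stage can be
exercised and calibrated without field data.

## The EMS procedure

A metacommunity is a set of local communities connected by dispersal. The
EMS framework reduces an incidence (presence-absence) matrix to three
ordered elements and reads an idealized structure off their signs and
significance.

**Ordination.** The incidence matrix (samples in rows, genera in columns;
presences are counts at or above a threshold, default 1, with all-zero rows
and columns pruned) is ranked by reciprocal averaging: site scores are
fill-weighted means of genus scores and vice versa, whose fixed point is
the first non-trivial correspondence-analysis axis. `reciprocal_averaging()`
offers the direct route (singular decomposition of the chi-square
standardized matrix, the default) and the classical iterative loop
(tolerance `1e-10`, at most 1000 passes); the two agree to numerical
precision, and the tests assert this. The axis sign is fixed so the first
row's score does not exceed the last row's in input order; ties in scores
are broken by input index. Neither choice affects any count statistic
downstream, which the test suite also asserts via order-reversal
invariance. Disconnected (block-diagonal) matrices are ordinated per block,
blocks concatenated by decreasing size, with a warning; they are never
re-glued silently.

**Coherence** counts embedded absences: zeros lying strictly inside a
genus' range (between its first and last presence along the ordered site
axis), plus, in the default `both_axes` mode, the analogous gaps inside
each site's range along the genus axis. A `columns_only` mode is available
since published analyses differ in this convention.

**Turnover** counts replacements: after filling each genus' range
(embedded absences set to present — the standard convention, with an
unfilled option for sensitivity checks), every (site pair, genus pair)
combination in which one genus is present at one site but not the other
while the second genus shows the opposite pattern counts once. For a genus
pair this equals `|A_i \ A_j| * |A_j \ A_i|` on the filled ranges.

**Boundary clumping** counts genus range boundaries per site (first and
last occurrence both count) and summarizes their aggregation with
Morisita's index of dispersion `I = n * sum(f_i(f_i - 1)) / (F(F - 1))`.
Significance uses the chi-squared dispersion statistic
(`sum((f - F/n)^2 / (F/n))`, `df = n - 1`), one-tailed toward the observed
side of 1: `I` significantly above 1 means clumped boundaries, below 1
evenly spaced boundaries.

**Null models and the Z-test.** Coherence and turnover are judged against
simulated matrices. The default EMS null is `row_fixed` ("r1"): each null
row keeps its site's richness, and presences land on genera with
probability proportional to observed prevalence. Every null matrix is
re-ordinated before its statistics are counted, exactly as the observed
matrix is. One set of null matrices is scored for both coherence and
turnover; the two Z-tests are computed from the same draws, which halves
the simulation cost without changing either marginal test. The default is
1000 null matrices. Significance is the two-tailed normal tail probability
of `z = (obs - mean_null) / sd_null`; an empirical p-value is available as
an option.

**Classification.** `classify_structure()` implements the decision tree:
non-significant coherence gives Random; significantly more embedded
absences than expected gives Checkerboard; with positive coherence,
significant turnover splits into Nested (replacements below the null mean)
versus gradient structures (above), which boundary clumping resolves into
Clementsian (`I` significantly above 1), Evenly spaced (significantly
below 1) or Gleasonian (neither). Non-significant turnover yields the
corresponding Quasi- structure, with the direction of the replacement
count against its null mean choosing the branch; nested subtypes (clumped,
stochastic, hyperdispersed loss) follow the same boundary rule. The
default significance level is 0.05 throughout, configurable. The decision
tree reproduces all 15 published labels of the reference summary table
shipped with the package (`reference_ems_stats()`), including every quasi-
and nested-subtype branch that table exercises.

## Co-occurrence: C-score and SES

The C-score is the mean number of checkerboard units over all unordered
genus pairs, `(Ri - S)(Rj - S)` for a pair co-occurring at `S` of their
`Ri` and `Rj` occupied sites. Its null distribution comes from the
fixed-fixed sequential-swap algorithm: attempted 2x2 checkerboard flips on
random row and column pairs, which preserve both margins exactly. The
chain burns in for `10 * fill` attempted swaps and takes one sample every
`fill` attempts (fill = number of presences), approximating independent
draws; the swap kernel is implemented in C++ and driven by R's RNG, so a
single seed reproduces the whole analysis. The default is 10,000 null
matrices. The standardized effect size `SES = (obs - mean)/sd` is read
against the conventional normal band: above 2, non-random segregation;
below -2, non-random aggregation.

Two definitional choices deserve note. The denominator of the C-score is
the number of unordered genus pairs `P(P-1)/2`, matching the definition of
an average over "all possible pairs of genera". And SES is the number of
null standard deviations, `(obs - mean_sim)/sd_sim`; a published variant
that divides by the simulated statistic itself is inconsistent with the
+/-2 normal-band interpretation and is treated as a typographical slip.

**What the fixed-fixed null can and cannot detect.** Total pairwise
co-occurrence `sum_pairs S_ij` equals `sum_r d_r(d_r - 1)/2`, a function of
site richness alone — every margin-preserving null conserves it, and the
C-score is convex in `S`. Concentrating co-occurrence (e.g. perfectly
co-placed genus pairs) therefore raises the C-score, and a perfectly
aggregated (nested) matrix is the unique member of its margin class, so
the swap chain freezes and the null degenerates. In practice the
fixed-fixed C-score detects segregation; aggregation is largely absorbed
into the margins, and the region below the null mean is a shallow floor.
The synthetic `aggregated_pairs` scenario honestly generates co-placed
pairs, and the test suite asserts its construction rather than a negative
SES that this statistic cannot deliver; the `segregated_pairs` scenario is
asserted to give SES above 2, which it does robustly.

## Distance decay: Mantel tests

Community dissimilarity is Bray-Curtis on the abundance tables
(via `vegan`); environmental distance is Euclidean on standardized
variables (zero-variance variables are dropped with a warning);
geographic distance defaults to great-circle kilometres on a 6371 km
sphere (via `geosphere`), with plain Euclidean-on-degrees as an
alternative, since survey descriptions alternate between the two
conventions. The Mantel statistic is the Spearman correlation of the
upper-triangle entries; its p-value permutes the labels of the second
matrix, one-tailed for positive association by default (the distance-decay
direction), `p = (1 + #[r_perm >= r_obs])/(1 + n_perm)` with 9999
permutations. `vegan::mantel` serves as an independent cross-check of the
statistic in the tests.

## Gradient importance

Site scores of the first ordination axis summarize the dominant
compositional gradient. `importance_analysis()` regresses them on the six
soil variables (SM, ST, pH, STC, STN, STP) plus longitude and latitude
with a 500-tree random forest and reports permutation importance (% rise
in out-of-bag MSE). Because importance values have no analytic null, each
variable's significance comes from refitting the forest on permuted
responses (default 100 permutations) and comparing the observed importance
with its own permuted distribution. This response-permutation null is the
simplest defensible choice; it is a design decision of this package, not a
claim about how any published analysis computed its stars. Collinear
predictors split importance between them — a known diagnostic caveat of
permutation importance, not corrected here.

## The synthetic survey

`generate_study_design()` emulates the survey frame end to end: four
stations spanning latitudes 40.8-50.25 N (with their mean annual
temperature and precipitation), three land covers, three replicate plots
and two sampling years — 72 samples; a 32-genus pool split evenly across
the four trophic groups (plant parasites PF, bacterivores BF, fungivores
FF, omnivores-predators OP); and at most 100 identified individuals per
sample (a few samples fall short, as identification does in practice).

Occupancy follows Gaussian niches on a suitability axis anchored to
latitude: each genus draws a niche centre across the station span and a
width of 0.9-2.4 latitude-equivalent units; each sample's position is its
station latitude plus a land-cover offset (+-0.8) and a plot-level
microhabitat displacement (SD 2.0 latitude-equivalent units). The
microhabitat term is what gives local (within-station) communities a real
gradient: without it, six samples per station differ only by noise and
every local unit classifies Random, unlike the surveys this emulates.
Abundances place one individual per presence and distribute the remainder
of the ~100-individual sample multinomially with log-series-like genus
weights (`x^k / k`, x = 0.85). Environmental variables track latitude
(soil carbon and nitrogen rise northward, pH and temperature fall) with
within-site noise, so Mantel and importance stages see realistic, known
signal.

`generate_metacommunity()` produces single-gradient scenarios with known
structure for calibration: Clementsian (compartments sharing jittered
boundaries; noise SD 0.5 gradient units by default), Gleasonian
(independent ranges drawn wholly inside the gradient — truncating ranges
at the ends would spuriously clump boundaries), nested (prevalence-ordered
subsets), evenly spaced, random Bernoulli, and the segregated/aggregated
pair designs. Generation is a pure function of (parameters, seed).

**What passing tests do and do not show.** The generators produce
single-axis, noise-controlled communities; real soil nematode data carry
sampling error, detection failure, multiple interacting gradients and
temporal turnover that these scenarios do not emulate. Recovery rates
measured on them (at 24 sites x 30 genera, 100 null matrices, 30 seeds per
structure: 100% for Clementsian and nested, ~97% for random, ~75-90% for
Gleasonian) calibrate the machinery, not the field performance of EMS.
The Gleasonian shortfall is informative: even ideal independent ranges
trip the boundary-clumping test somewhat more often than its nominal level
because a finite gradient biases boundary positions toward the interior,
and such cases classify as the adjacent Clementsian branch.

## Numerical and reproducibility choices

- All simulation sizes are configurable; defaults are 1000 (EMS), 10,000
  (co-occurrence), 9999 (Mantel), 500 trees / 100 permutations
  (importance). The test suite and acceptance script run scaled-down
  versions (100-300 null matrices, 30-200 replicates) chosen to keep the
  whole suite under a minute while leaving Monte-Carlo error well inside
  the asserted tolerances.
- A single global seed fans out to per-stream seeds through a counter-based
  mixing map (`derive_seed()`), so independent randomizations are
  reproducible and order-independent; the sequential-swap chain, being a
  Markov chain, is seeded once per analysis.
- Degenerate inputs fail loudly with a dedicated condition class: empty
  matrices after pruning, one-row/one-column ordinations, flat ordination
  scores (no gradient), conserved statistics (zero null SD), constant
  distance matrices.
- The two sampling years are pooled into one matrix per analysis unit by
  default, matching the one-row-per-unit layout of published EMS tables; a
  `years` argument allows per-year analysis.
- Singleton genera are retained (no prevalence filtering) unless a caller
  prunes them explicitly.

## Known limitations

- Only the first ordination axis is used; secondary compositional axes
  are ignored by design.
- The fixed-fixed C-score cannot flag aggregation (see above); users who
  need aggregation tests should pair the C-score with a null that frees
  one margin.
- The boundary-clumping chi-squared test inherits the finite-gradient
  edge bias discussed above.
- Mantel tests are marginal; no partial Mantel or distance-based RDA is
  provided.
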