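---
title: "Quantifying community-level biotic associations: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community-level biotic associations: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioticnet)
```

## The problem

Correlation (or covariance) networks over microbial taxa describe
*co-occurrence*, not interaction. Co-occurrence is the joint outcome of
at least three assembly processes: dispersal limitation (taxa co-occur
because space structures both), environmental selection (taxa co-occur
because they respond to the same abiotic conditions), and genuinely
biotic association. `bioticnet` operationalises the exclusion argument:
an edge whose paired abundances track neither geographic distance nor
environmental dissimilarity is *putatively* biotic — putatively, because
exclusion can never rule out unmeasured drivers or drift.

## The model, stage by stage

### Taxon filtering

Correlations among rare taxa are unstable, so the default pre-filter
keeps a taxon only if it occurs (abundance > 0, no pseudocount) in
strictly more than 25% of samples *and* its mean relative abundance is
at least `1e-5` (0.001%). The abundance criterion is ambiguous in common
usage (per-sample, maximum, or mean); we fix **mean across all samples**
as the default and expose `abund_stat = "max"` as the alternative. Both
gates are applied jointly (AND), so their order is immaterial.

### Network inference

Pairwise Pearson or Spearman correlation with the t-transform p-value
`t = r sqrt(n-2)/sqrt(1-r^2)` on `n-2` df (two-sided). Zero-variance
taxa get `r = 0, p = 1` with a warning instead of `NaN` — degenerate
columns must not poison the matrix. Benjamini–Hochberg q-values are
computed over the upper triangle, and an edge is kept iff `|r| > r_min`
(strict) and `q < q_max` (strict). The significance gate used alongside
the conventional `r > 0.6` cut-off is not standardised in the field; we
default to BH `q < 0.05`. Inverse-covariance methods are deliberately
not reimplemented — they are mature standalone tools — and their signed
edge lists are imported with full invariant checking instead.

### The RMT threshold scan

Choosing `r_min` by hand is arbitrary. The random-matrix-theory
criterion scans a grid (0.30–0.95, step 0.01): at each candidate the
matrix is hard-thresholded, taxa without surviving partners are dropped,
and the nearest-neighbour spacing distribution (NNSD) of the *unfolded*
eigenvalues is tested against the Poisson law `P(s) = e^{-s}` by
chi-square (spacings truncated at `s = 3`, `ceiling(sqrt(n))` bins,
expected masses renormalised over `[0, 3]`). While dense correlated
noise remains, spacings show GOE-like level repulsion and the fit
fails; once only genuine modular structure survives, eigenvalues from
independent blocks interleave independently and the fit passes. The
chosen threshold is the smallest candidate with fit `p > 0.05` and at
least 50 eigenvalues (both exposed).

Two numerical choices matter here:

* **Unfolding stiffness.** The empirical spectral CDF is a step
  function. A smoothing spline tuned by GCV chases the steps, mapping
  each eigenvalue essentially onto its rank; all spacings collapse to
  ~1 and the chi-square rejects *everything*, including genuinely
  modular spectra (we observed fit p < 0.02 across the whole grid). The
  purpose of unfolding is to remove only the global density trend, so
  the spline's equivalent degrees of freedom are fixed at 5 by default
  (`unfold_df`).
* **Degeneracies.** Exactly repeated eigenvalues (within `1e-8`) are
  collapsed before unfolding; block-constant submatrices otherwise
  flood the NNSD with zero spacings.

A scan can legitimately find nothing (`found = FALSE`); callers fall
back to a fixed `r_min`, as `run_pipeline(use_rmt = TRUE)` does.

### Per-edge link tests

For an edge (i, j) the sample × sample distance of the *joint* 2-column
abundance submatrix (Bray–Curtis by default, double-zero pairs defined
as distance 0; Euclidean available) is Mantel-tested against (a)
geographic distance — haversine great-circle km on Earth radius
6371 km, optionally combining elevation differences (km) in Euclidean
norm — and (b) environmental dissimilarity — Euclidean on z-scored
selected variables. When several variables form one environmental
matrix, a greedy screen in caller priority order drops any variable
with |Spearman ρ| ≥ 0.5 against an already-retained one.

The Mantel test correlates upper-triangle entries (Spearman by default
for link tests) and permutes sample labels of the second matrix. The
p-value is one-sided in the distance-decay direction with the identity
permutation included: `p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`,
hence never 0. For `n` small enough that `n! − 1 ≤ n_perm`, all `n!`
relabelings are enumerated and `p = #{r_perm ≥ r_obs}/n!` exactly.
Spearman permutations reuse the triangle's rank multiset — relabeling
maps unordered pairs to unordered pairs, so ranks are computed once.

A factor "explains" an edge when `p < α` **and** `r > 0`: dispersal
limitation and environmental filtering predict distance–dissimilarity
*increase*, so a significantly negative Mantel r is not treated as
explanatory. The written description of the procedure is sequential
(space first, then environment), but a strict sequence cannot produce
the "overlap of dispersal limitation and environmental filtering" class
that the framework reports; we therefore test both factors for every
edge and read the four classes off the 2×2 significance pattern.
Per-edge multiplicity is *not* corrected by default (link tests run at
a fixed per-edge level); `fdr = TRUE` applies BH per factor if wanted.

### Quantification

In the biotic-filtered network, taxon j's positive connectedness is the
mean weight of its positive edges (0 if none), and symmetrically for
negative. The mean runs over the taxon's *incident links*; a
cohesion-style variant dividing by `|taxa| − 1` sits behind
`denominator = "all_taxa"`. Community strengths are the matrix products
of the relative-abundance matrix with the two connectedness vectors —
so `positive_strength ∈ [0, max_j c⁺_j]` by convexity, and both
strengths are linear in the profile. Count tables are converted to
relative abundance with a notice; the weighting is defined on relative
abundance throughout.

### Consequence models

`forward_select_ols()` adds, at each step, the candidate with the
largest adjusted-R² gain among those with partial-F `p < alpha_enter`
(default 0.05 — the conventional level, since "forward selection" alone
names no criterion) and gain above an improvement floor (0.001).
Near-collinear candidates (design condition number > 1e10) are skipped
with a warning. The final fit is an ordinary `lm`, and its coefficient
table is reported verbatim. `mantel_beta()` converts scalar factors to
1-D Euclidean (absolute-difference) distances — standard Mantel
practice — and tests each against Bray–Curtis community dissimilarity.
Random-forest importances and dbRDA ordinations are intentionally out
of scope: both are off-the-shelf procedures a user can run on the
exported strengths.

## What the synthetic generator does and does not emulate

`generate_community()` states a world: samples uniform in a ~50 km
lon/lat box at 3000–3500 m elevation; one standardised environmental
gradient independent (by default) of a smooth linear spatial field;
planted pairs whose log-abundances are `β·gradient + N(0, σ)` (env),
`β·field + N(0, σ)` (space), or a latent bivariate normal with
correlation ±ρ independent of both (biotic); independent log-normal
noise taxa (log-mean −3, log-sd 1, chosen to give a realistic
rank-abundance curve). Defaults — 60 samples, 100 noise taxa, 20+20+20
pairs, β = 2, σ = 0.3, ρ = 0.9 — are the strong-effect recovery
scenario the acceptance suite exercises. Zero inflation is emulated by
quantile truncation (each taxon's lowest 30% of values zeroed), not by
a hurdle model; rows are then renormalised.

This generator does **not** emulate compositional coupling beyond row
normalisation, phylogenetic structure, dynamical (Lotka–Volterra)
feedbacks, sequencing depth variation, or overlap-class pairs unless
`env_space_cor` is raised. A green recovery test therefore establishes
that the pipeline separates the three planted signals under strong,
identifiable effects — not that it resolves weak or confounded effects
in real surveys.

## Numerical conventions and degenerate inputs

* Distances live in `stats::dist` objects with sample labels; symmetry
  and zero diagonals come with the container.
* Zero-variance distance triangles make the Mantel r undefined: the
  test returns `r = 0, p = 1` with a warning.
* Zero-sum samples cannot be normalised (error naming the sample);
  all-zero rows arising from sparsity truncation in the generator are
  dropped before normalisation.
* Networks canonicalise unordered pairs (`taxon_a < taxon_b`,
  lexicographic order) so writers are byte-reproducible; zero-weight
  edges are rejected at construction.
* All stochastic entry points (`mantel_test`, `assign_processes`,
  `mantel_beta`, `generate_community`) take explicit integer seeds;
  `assign_processes` derives one sub-stream per edge and factor, so
  results are invariant to edge evaluation order.

## Known limitations

Partial Mantel and multiple regression on distance matrices are not
offered — exclusion is per factor, so a spatially structured
environment inflates the overlap class rather than being partialled
out. The RMT criterion is a goodness-of-fit test at one significance
level, and on small spectra (~50–100 eigenvalues) its pass/fail
boundary is noisy; treat the chosen threshold as a starting point, not
an oracle. Imported networks are trusted after invariant checks — no
attempt is made to re-derive their significance.
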