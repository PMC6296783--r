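---
title: "Methods: plant diversity and soil multifunctionality"
author: "soilmultifun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant diversity and soil multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilmultifun)
```

## The problem this package addresses

Grassland experiments that factorially cross sown plant species richness
with global-change drivers (elevated CO2, nitrogen enrichment) ask whether
biodiversity keeps delivering multiple ecosystem functions under future
conditions. `soilmultifun` implements the complete analysis chain for such
a design with four soil functions — root biomass (g m^-2), soil basal
respiration (ul O2 h^-1 g^-1 dry soil), microbial biomass C (ug C g^-1 dry
soil), and the water-stable aggregate fraction — from raw assay readings
through diversity and functional-diversity indices, multifunctionality
statistics, split-plot ANOVA, correlation structure, and a recursive path
model. A synthetic data generator emulates the 364-plot split-plot design
(six rings, three per CO2 level; 32/32/15/12 replicates per CO2 x N cell
at richness 1/4/9/16) so every stage is testable without field data.

## Assay conversions

Two functions come from an O2-microcompensation respirometer.
Basal respiration is the mean hourly O2-consumption rate over a late,
stable window; the default is hours 14–24 *inclusive* (11 readings) —
endpoint inclusivity is a documented choice and both window bounds are
arguments. For substrate-induced runs, the maximum initial respiratory
response (MIRR) is the mean of the three lowest readings within the first
10 h (the plateau between the disturbance peak and the microbial growth
peak), and microbial biomass C is `38 * MIRR`; the factor is exposed as an
argument. The aggregate fraction is
`(water-stable fraction - coarse matter) / (initial mass - coarse matter)`
per 4.0-g duplicate, and duplicates are averaged *after* the per-duplicate
fraction so each keeps its own denominator.

## Taxonomic indices

All indices work on relative abundances and are scale-invariant, so
percent cover and proportions are interchangeable. Shannon diversity uses
natural logs (the convention of this literature; the base is an
argument). Two conventions needed a decision:

* A plot in which every sown species went extinct receives **0 for every
  diversity index** (the empty-community convention of the analysis this
  package reimplements). This rule takes precedence over the next one.
* The Shannon evenness `H / log(S)` of a *surviving monoculture* is
  undefined (`log 1 = 0`); it is reported as `NA` and drops out of
  evenness analyses rather than being forced to 0 or 1.
* Simpson evenness is the inverse Simpson concentration divided by
  realized richness, `(1 / sum p_i^2) / S` — the standard form of the
  index when the source names it without a formula. It is its own
  function and trivially swappable.

## The functional trait space

Five traits (plant height, SLA, LDMC, leaf N, seed mass) describe light
preemption, resource capture and reproduction. Species dissimilarity is
the classical Gower distance for quantitative traits: range-normalized
absolute differences averaged over traits, bounded in [0, 1]. Principal
coordinates analysis embeds the distance matrix; when negative
eigenvalues occur the Cailliez correction is applied by default (the
convention of distance-based FD software; Lingoes and no correction are
selectable). Axes with eigenvalues below 1e-9 times the largest are
dropped.

The four community-weighted indices are:

* **FDis** — abundance-weighted mean distance to the abundance-weighted
  centroid. Defined for any non-empty community (0 for monocultures),
  which is why it is the mediator used in the path model: it exists for
  every plot.
* **FRic** — convex-hull volume of the present species divided by the
  pool's hull volume on the same axes. Computed exactly by brute-force
  facet enumeration (closed forms in 1-D/2-D), which is exact at pool
  sizes of a few dozen species; verified against an independent qhull
  implementation in the tests. The number of hull axes is reduced to
  (minimum richness among plots with >= 3 species − 1), mirroring
  standard dbFD behaviour, and additionally capped (default 5) because
  hull estimation in high dimension is both statistically fragile and
  combinatorially explosive.
* **FEve** — Villéger's minimum-spanning-tree regularity index. The MST
  is built by Prim's algorithm with ties in edge weight broken by
  species-name lexicographic order, so results are deterministic.
* **FDiv** — Villéger's divergence index around the centre of gravity of
  the hull vertices, on the same (reduced) axes as FRic.

Plots with fewer than three species get `NA` for FRic/FEve/FDiv;
all-extinct plots get 0 for all four indices (precedence as above).
Synthetic traits are pool-level constants: the generator carries no
treatment-specific trait variation (a documented divergence from field
datasets in which seed mass and leaf N can vary by treatment).

## Multifunctionality

Functions are min-max standardized to [0, 1] **once across the analysed
plot set** (not per treatment). The averaging approach is the plot mean
of the four standardized values. The multiple-threshold approach counts,
per plot, the functions whose *raw* value is at or above t% of that
function's maximum observed value ("at or above", so `>=`), and the
package reports the OLS slope (and SE) of that count on log sown richness
for every t in 1–99% plus the focal grid {20, 40, 60, 80}%. The log-linear
regressor matches the PSR term used throughout the ANOVA layer; a
linear-richness option exists because axis conventions differ between
reports. Evenness of multiple functions treats the four standardized
values as species abundances: `q_f = std_f / sum(std)`,
`H = -sum(q_f log q_f)`, evenness `H / log 4`; an all-zero plot gets 0 by
the same empty-community convention.

## The split-plot ANOVA

Each response is fit with CO2, N, log(PSR), all interactions, and ring
nested within CO2, using sum-to-zero factor coding, a centred covariate,
and Type III sums of squares (each term adjusted for all others via
full-vs-reduced projections). Centring plus sum-to-zero coding makes
Type III and sequential SS coincide on balanced designs, a property the
tests exploit. CO2 is the whole-plot factor: its F uses the ring-within-
CO2 mean square, all other terms the residual.

Degrees-of-freedom accounting is reported both ways. The conventional
nested accounting gives ring-within-CO2 4 df, model rank 12, residual
`n − 12`. The alternative bookkeeping that counts the ring block with 6
df (13 model df, residual `n − 14`) is carried in the attribute
`df_residual_caption`, because some widely used software reports the
design that way; on 315 complete-case plots this accounting yields 301
residual df. All F and p values use the conventional strata. An optional
Satterthwaite mode constructs, for unbalanced ring sizes, the linear
combination of ring and residual mean squares whose expectation matches
the CO2 numerator under the null (coefficients from the exact trace
identities of the projection matrices) with Satterthwaite's approximate
df; on balanced data it reduces to the classical test. Sensitivity
switches refit excluding monocultures or with realized instead of sown
richness; no cross-response multiplicity correction is applied, matching
per-response reporting.

## The recursive path model

The final structure has four observed variables — log richness, FDis,
evenness of functions, multifunctionality — and four paths: richness to
each mediator, each mediator to multifunctionality, with no direct
richness effect and uncorrelated mediator errors. For recursive observed-
variable models with uncorrelated errors, equation-wise OLS *is* the ML
solution; the tests verify this against a numerical optimizer of the
covariance likelihood. Conventions: the ML covariance (divisor n) is
used; fit is summarized by `chisq = (n − 1) F_ML` against the saturated
model; `df = p(p+1)/2 − k` (here 10 − 8 = 2); `AIC = chisq + 2k`.
Standardized coefficients use model-implied standard deviations.
`compare_paths()` quantifies single-path modifications by refitting (an
AIC difference of exactly +2 for a useless path on exact-moment data);
explicit modification-index derivatives are deliberately out of scope.

## The synthetic generator and its calibration

Each soil function is
`y = mu + a log(S) + b [CO2] + c [N] + ring + lambda z + eps`, with
independent per-function ring effects, a shared standard-normal latent
factor z coupling respiration and microbial biomass, and Gaussian
residuals; draws outside the physical range are redrawn, not clipped, to
avoid boundary point mass. Covers come from a symmetric Dirichlet over
the surviving sown species whose concentration shrinks under N (and more
weakly CO2) enrichment — the Dirichlet family is an assumption, flagged
as such, since the realized cover distribution of the field data is not
published. Extinctions are per-species Bernoulli with a logit linear in
sown richness and N.

The defaults were fixed once by a desk calculation, not by iterating on
test outcomes:

* With n = 364 and the design's log-richness spread
  (`sd(log S) ≈ 1.0`), an F statistic near F* for the richness term
  requires `a / sigma_noise ≈ sqrt(F*) / (sd(log S) sqrt(n))`. Targeting
  the reported effect sizes (F ≈ 80 for root biomass and microbial
  biomass, ≈ 23 for respiration, ≈ 3 for aggregates) gives
  a = 70, 47, 0.6, 0.01 at noise SDs 150, 100, 2.5, 0.12 on means of
  500, 400, 12, 0.55.
* Means sit at least ~3 noise SDs above zero so that positivity redraws
  are negligible (< 0.1% of draws) and leave regression slopes unbiased —
  an earlier, noisier parameterization visibly attenuated monoculture
  means through truncation, which the slope-recovery test is designed to
  catch.
* The latent loadings solve
  `r = (a_r a_m var(log S) + l_r l_m) / (sd_r sd_m)` for r^2 = 0.45, the
  one strong function pair; all other pairs share only the richness
  signal and stay below r^2 ≈ 0.1.
* Under this calibration the averaging multifunctionality of 16-species
  mixtures exceeds monocultures by roughly 30% (20–35% across seeds);
  the field value is 40%, and the difference is an honest consequence of
  min-max standardization against Gaussian extremes rather than a
  tuning target.

What the generator does **not** emulate: 17 years of community dynamics,
phenology, within-plot spatial structure, treatment-dependent traits,
non-Gaussian skew in the functions, or assay-level missingness (analyses
needing the 315-complete-case count blank a seed-chosen plot subset).
Passing tests therefore demonstrate correctness of the statistical
machinery under the design's effect structure, not field realism.

## Numerical choices and problem sizes

Tolerance choices: PCoA axes kept above 1e-9 of the leading eigenvalue;
hull facet tests at 1e-9 of the coordinate scale; MST ties at 1e-12.
Degenerate inputs have defined behaviour throughout: zero-range traits,
constant functions, all-zero communities and cyclic path sets raise
informative errors; undefined indices propagate as `NA` (empty cells in
CSV output).

The test suite sizes its simulations for tight feedback while keeping
real statistical power: 10^4 random communities for the FEve/FDiv bounds,
1000 replicates for the size of the richness test (with a 95% binomial
band), 500 replicates for slope-recovery coverage and for standardized
path-coefficient recovery at n = 364, and exact-moment samples (whitened,
then recoloured) wherever "recovered to machine precision" is the claim.

## Known limitations

* FRic/FDiv depend on the axis cap; hull volumes in more than ~6 axes
  are neither computed (cost) nor advisable (sparsity).
* The Satterthwaite mode approximates one specific unbalanced-design
  correction; it does not reproduce any particular proprietary
  implementation's fractional df.
* The path layer covers recursive observed-variable models only — no
  latent variables, no correlated errors.
* `threshold_slope_profile()` uses OLS on counts; a generalized linear
  model variant is a possible extension.
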