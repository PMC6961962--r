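---
title: "Methods: nutrient-color classification and change analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-color classification and change analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrientcolor)
```

## The nutrient-color view of lakes

Lake condition is usually summarised on a single trophic axis (nutrients,
chiefly total phosphorus). The nutrient-color paradigm crosses that axis
with true water color — a proxy for chromophoric dissolved organic matter —
to give four classes:

* **blue**: TP ≤ 30 µg/L and color ≤ 20 PCU (oligotrophic, clear);
* **green**: TP > 30 and color ≤ 20 (eutrophic);
* **brown**: TP ≤ 30 and color > 20 (dystrophic, stained);
* **murky**: TP > 30 and color > 20 (simultaneously enriched and stained).

The thresholds are conventions from the lake-classification literature, not
fitted quantities; `nc_thresholds()` makes them explicit and overridable.
Two boundary decisions matter and are enforced consistently: thresholds are
*inclusive on the blue/brown side* (a lake at exactly 30 µg/L and 20 PCU is
blue), and the four rules partition the non-negative quadrant, so every
lake with measured TP and color receives exactly one label. `nc_classify()`
carries a property-style test suite for the partition and for monotonicity
(raising TP can only move a lake blue→green or brown→murky; raising color
only blue→brown or green→murky).

"Extreme" members of each class are defined by quartiles of the classified
data: blue lakes below the class Q1 in both TP and color, murky lakes above
the class Q3 in both, and the mixed rules for green (high TP, low color)
and brown (low TP, high color). Quartiles use the type-7 (linear
interpolation) estimator, R's default, since no other convention is
specified in the source material for these summaries; membership uses
strict inequalities, so a class with constant values has no extreme lakes.

## Design-based estimation of class shares

National lake surveys sample from a stratified randomized design; each
sampled lake carries a design weight equal to the number of population
lakes it represents. The share of the population in class $c$ is estimated
by the Horvitz–Thompson ratio

$$\hat P_c = \frac{\sum_i w_i\,\mathbf 1[\text{class}_i = c]}{\sum_i w_i},$$

which is invariant to uniform rescaling of the weights
(`ht_proportion()`).

### Local-neighborhood variance

For spatially balanced designs, a variance estimator that compares each
site with its spatial neighbours is less conservative than the
simple-random-sampling (SRS) formula because nearby sites absorb spatial
trend. `local_mean_variance()` implements a single-pass version:

1. linearised residuals $t_i = w_i(z_i - \hat P_c)/\sum w$;
2. each site's neighbourhood is itself plus its 4 nearest neighbours by
   great-circle distance;
3. neighbourhood weights are proportional to inverse distance rank
   (1, 1/2, ..., 1/5), normalised to sum to one;
4. the estimator pools $\sum_i \sum_j a_j (t_{(ij)} - \bar t_i)^2$, where
   $\bar t_i$ is the weighted local mean.

A single smoothing pass (rather than iterative row/column balancing of the
neighbourhood weight matrix) biases this sum downward by the factor
$1 - \sum_j a_j^2$ per site under independent residuals; we divide by that
factor, which makes the estimator exactly unbiased in the independent case
while preserving its advantage under spatial structure. This correction
follows from a two-line expectation calculation and is applied
unconditionally. With fewer than `neighborhood_size + 2` sites, or without
coordinates, the estimator falls back to the weighted SRS variance with a
warning.

Confidence intervals are normal-approximation ($\pm 1.96\,\mathrm{SE}$),
truncated to $[0, 100]$. On simulated stratified surveys of 405 lakes
(nine strata of 45) the 95% intervals cover the generator's true blue
share 93–94% of the time over 500 replicates; part of the residual gap to
the nominal level is the familiar undercoverage of Wald intervals for
proportions, which shrinks with survey size. The test suite pins the
coverage inside [0.93, 0.97] at that problem size.

### Change between two surveys

`change_analysis()` differences per-class estimates between surveys,
treating the surveys as independent: $\widehat\Delta = \hat P_2 - \hat
P_1$, $\mathrm{SE}_\Delta = \sqrt{\mathrm{SE}_1^2 + \mathrm{SE}_2^2}$,
significance when the 95% interval excludes zero. The two national surveys
share a minority of revisited lakes, which induces a small positive
covariance the independence assumption ignores; exploiting it would need
the joint inclusion structure, which the released estimates do not carry,
so the intervals here are mildly conservative for the change.

## Change vectors and circular statistics

Each lake sampled in both surveys defines a vector in (ΔTP, Δcolor)
space. Magnitude is the Euclidean norm in the mixed native units (µg/L and
PCU, no standardisation — the published ranges confirm the same
convention; a `standardize` flag exists but is off by default). Direction
is measured counterclockwise from the +ΔTP axis, so 45° means equal
increases on both axes and angles below 45° mean proportionally larger TP
increases. Zero-length vectors have no direction: they are excluded from
circular statistics but keep magnitude 0 in magnitude comparisons.

* `circular_mean()` is the direction of the resultant of unit vectors,
  flagged unstable when the resultant length is ~0.
* `bootstrap_mean_angle_ci()` computes a percentile arc on the circle:
  bootstrap means are wrapped to deviations in (−180°, 180°] around the
  point estimate before taking quantiles, so the arc always contains the
  estimate. 999 resamples by default, seeded.
* `rao_spacing()` tests uniformity via $T = \tfrac12\sum_i |T_i -
  360/n|$ over sorted-angle spacings (including the wrap-around). $T = 0$
  for perfect spacing and $360 - 360/n$ when all angles coincide. The
  p-value is Monte-Carlo (default 10,000 seeded uniform replicates) rather
  than interpolated from published critical-value tables — exact at any
  sample size, and a precomputed null sample (`rao_null()`) can be shared
  when scoring many samples.
* `vector_group_anova()` compares angle or magnitude across origin classes
  with a standard one-way ANOVA. Angles are treated linearly, matching the
  usual practice for concentrated direction data; this is unreliable when
  directions straddle the 0°/360° cut, which the documentation flags.

## Plankton community processing

Phytoplankton biovolume (µm³/mL) is converted to dry biomass assuming
unit wet density (1 µm³ = 10⁻⁶ µg), a per-mL→per-L scale-up, and a 20%
wet-to-dry fraction: 10⁶ µm³/mL → 200 µg dw/L. Zooplankton taxa counted
in both the 50 µm and 150 µm mesh nets are averaged per site and taxon
(`merge_mesh_duplicates()`, idempotent); taxa seen in a single mesh pass
through unchanged, the natural reading when the duplication rule is
silent about them.

Rare-taxon screening retains a taxon only if it contributes ≥ 5% of at
least one sample (`filter_rare_taxa()`), applied first at order level and
then at genus level within retained orders. The alternative literal
reading — drop a taxon that is below 5% in *any* sample — would empty
most real matrices, so the "reaches 5% somewhere" reading is used for
both ranks. `aggregate_rank()` sums genera into orders and conserves
per-site totals exactly. `zp_ratios()` reports zooplankton:phytoplankton
biomass ratios (total, crustacean-only, rotifer-only); sites with zero
phytoplankton biomass keep their row with undefined (`NA`) ratios.

## Group comparisons

The comparison stack is implemented from scratch, with the established
implementations used as independent cross-checks in the tests:

* **Kruskal–Wallis** with tie correction; p-value from the χ²
  approximation, or from seeded label permutations for small samples
  (checked against exhaustive enumeration at n ≤ 8, and against
  `kruskal.test` under ties).
* **Dunn's post-hoc** pairwise mean-rank z tests with tie correction,
  two-sided, Bonferroni-adjusted over all reported pairs (capped at 1).
  With two groups $z^2$ equals the tie-corrected H — asserted
  numerically. `bonferroni_alpha()` exposes the family-level α/m rule
  (α = 0.05, m = 14 tests in the motivating analysis → 0.0036).
* **Bray–Curtis** dissimilarity on square-root-transformed values by
  default. It is a semi-metric: bounded in [0, 1], symmetric, zero
  diagonal, but the triangle inequality is not guaranteed and not
  asserted. A pair of all-zero sites is undefined (`NA`) and such sites
  must be removed before PERMANOVA/NMDS; the pipeline drops them with a
  logged count.
* **PERMANOVA** (single factor, free label permutations): pseudo-F from
  the within/between decomposition of squared dissimilarities,
  $R^2 = SS_B/SS_T$, $p = (1 + \#\{F^* \ge F\})/(n_{\text{perm}} + 1)$.
  Matches `vegan::adonis2` to 10 decimal places on the statistic and
  agrees with full enumeration at n = 6.
* **NMDS** minimising Kruskal stress-1 by alternating isotonic regression
  (via `stats::isoreg`, primary tie treatment) with a Guttman-transform
  update, plus a step-halving line search that guarantees the stress
  trace is monotone non-increasing — the property the tests assert.
  Initialisation is classical metric scaling plus random restarts
  (default 20); convergence when stress improves by < 10⁻⁶ over a
  10-iteration window. Exactly embeddable configurations are recovered
  with stress < 0.01.

## The synthetic generator

`synthetic_config()` fixes the study conditions for every simulation-based
test; the defaults are not tuning knobs:

* nine ecoregion strata, 110 lakes sampled per stratum (990 per survey,
  matching the ~1000-lake national surveys), design weight =
  population/sample per stratum;
* class mixture blue/green/brown/murky = 45.7/20.8/10.0/23.5%, the
  published 2007 national shares;
* per-class TP and color drawn from lognormals truncated to the class box,
  with parameters calibrated (`calibrate_truncated_lognormal()`, a
  least-squares fit on the log scale) so the *truncated* quartiles match
  the published class quartile summaries — e.g. blue TP (10, 16.5, 24).
  Truncation guarantees classification recovers the intended class;
* paired-year drift: additive in native units, direction von Mises around
  32.68° (the published mean direction) with concentration κ = 2,
  magnitude lognormal (median 25, log-sd 1) floored so TP and color stay
  non-negative; 39% of lakes marked as revisits (401/1028). Class labels
  in the second survey are always re-derived, never carried over;
* communities: per-site order compositions are Dirichlet draws around
  class means (murky lakes carry ~2× the blue rotifer share; Diplostraca
  dominates everywhere), total biomass lognormal around the published
  class medians (zooplankton 49.2/88.4/54.7/150.0 µg dw/L for
  blue/green/brown/murky), genera split within orders, and a subset of
  zooplankton taxa duplicated across both mesh records so the merging
  step is exercised. An `overdispersion` of 0 collapses compositions to
  the class means exactly.

What the generator does *not* emulate: spatially balanced (GRTS) site
selection — coordinates are uniform within stratum boxes — seasonal
dynamics, measurement error in color reading, and the heavy
lake-area/land-cover covariate structure of real surveys. Passing tests
therefore demonstrate estimator correctness under the stated model, not
robustness to every feature of field data.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to balance Monte-Carlo error
against runtime, stated here as the package's own defaults: 500 replicate
surveys of 405 lakes for interval coverage; 1,000 draws of 60 sites for
the variance-ratio check; 5,000 samples of 50 angles (against a shared
20,000-replicate null) for the Rao test's type-I error; 500 runs of 401
angles with 999 bootstraps for mean-direction coverage. All randomised
routines take explicit integer seeds and save/restore the caller's RNG
state, so results are bit-reproducible and independent of call order.
`run_full_analysis()` derives stage seeds from one master seed and writes
a manifest with an MD5 hash of every output file.

## Known limitations

* The independence assumption in `change_analysis()` (above) makes change
  intervals slightly conservative when surveys share revisited lakes.
* Linear treatment of angles in the ANOVA is only meaningful for
  concentrated directions away from the circular cut.
* Bray–Curtis being a semi-metric means NMDS configurations can embed it
  only approximately; stress ≥ 0.2 indicates an unreliable 2-D map and is
  reported, not hidden.
* The local-mean variance estimator assumes coordinates are informative
  about the design's spatial balance; with arbitrary coordinates it simply
  reproduces SRS-like behaviour on average.
* Zooplankton length–weight biomass regressions are out of scope: biomass
  is expected as an input column, as in the released survey tables.
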