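---
title: "Quantifying coral assemblage structure from colony morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coral assemblage structure from colony morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The structural complexity of a reef — the amount and quality of habitat its
corals provide — is largely set by colony growth forms. Growth forms are
categorical, which makes them awkward to fold into quantitative monitoring.
`coralfd` turns routine survey data (a species list with growth-form codes,
and percent cover per transect and year) into a quantitative description of
morphological diversity and of how a disturbance such as a bleaching event
erodes and rebuilds it.

The pipeline has five stages, each usable on its own:

1. **Traits and entities.** Species are coded on eight binary growth-form
   traits (arborescent, bushy, table, foliose, column, massive, encrusting,
   unattached). A species may carry more than one trait — free-living
   fungiids, for instance, are both massive and unattached — which is how
   growth-form plasticity enters the analysis. Each unique trait combination
   is a *functional entity* (FE); with 8 binary traits there are
   $2^8 = 256$ conceivable combinations, and a real pool realizes a small
   fraction of them.
2. **Functional space.** Gower dissimilarity among species (on binary
   traits, the proportion of mismatching traits), Cailliez correction,
   principal coordinates analysis; the resulting axes form a fixed
   morpho-functional space in which every assemblage through time is
   placed. Trait vectors (per-trait correlations with the axes) label the
   directions of the space.
3. **Community indices.** Per transect and year: community-weighted trait
   means (CWM), convex-hull functional richness (FRic), functional evenness
   (FEve), divergence (FDiv), dispersion (FDis), and Rao quadratic entropy
   (Q).
4. **Redundancy structure.** With $N$ species spread over $FE$ entities
   with $n_i$ species each:
   $$FR = \frac{\sum_i n_i}{FE} = \frac{N}{FE}, \qquad
     FV = \frac{FE - \sum_i \min(n_i - 1, 1)}{FE}, \qquad
     FOR = \frac{\sum_i [\max(n_i, FR) - FR]}{N},$$
   reported as percentages for FV and FOR. A constrained permutation null
   model tells whether species are packed into entities more unevenly than
   chance.
5. **Temporal inference.** Yearly means ± SE over transects, Welch and
   paired t-tests between years, multiplicity adjustment, and Pearson
   correlations of each assemblage metric with richness.

## Numerical and design choices

**Gower on binary traits.** Binary traits are treated as range-1
quantitative variables, so the per-pair dissimilarity is the mean absolute
difference over usable traits — the simple mismatch proportion. Traits with
zero range in the pool carry no information and are dropped from the
denominator with a warning rather than silently diluting distances.

**Species, not entities, in the embedding.** The dissimilarity matrix is
computed among species; members of one entity are coincident points, and
entity coordinates are the shared member coordinate. Distances between
entities therefore measure morphological difference directly, and
species-level weights can be aggregated to entities without moving any
point.

**Cailliez correction.** Binary Gower matrices are generally
non-Euclidean; the smallest additive constant making the matrix Euclidean
is found as the largest real eigenvalue of the standard $2n \times 2n$
companion system and applied to off-diagonal entries. The corrected matrix
reconstructs exactly from all positive principal axes (the test suite
checks the round trip to $10^{-8}$).

**Axis retention and signs.** Axes with eigenvalue above
$10^{-8}\lambda_{max}$ are kept internally; index computation uses the
first two by default, matching the two-dimensional hulls and trait-vector
plots the method is built around (the `axes` argument exposes the choice —
published toolboxes differ in their internal default, so it is explicit
here). Eigenvector signs are fixed deterministically: the
largest-magnitude loading on each axis is made positive, with magnitude
ties resolved to the smallest species label so results are invariant to row
order.

**One fixed space.** The space is built once from the full species pool
and reused for every year and transect. Yearly hulls are then nested in a
common coordinate system and comparable; this is what makes "the hull
shrank after the disturbance" a meaningful statement.

**CWM convention.** A multi-trait species contributes its full cover to
each of its traits, so per-trait percentages can sum above 100 across
traits. This keeps each trait's CWM interpretable as "percent of coral
cover presenting this trait"; a `normalize` option rescales profiles to
sum to 100 when a composition is wanted instead.

**Support rules.** Hull- and MST-based indices (FRic, FEve, FDiv) need at
least three functionally singular (distinct-coordinate) entities and a
non-degenerate hull; transects below that support get `NA` with the reason
recorded, and paired year comparisons use only transects defined in both
years. FDis and Q are defined down to a single species (both 0 there).
MST ties are broken lexicographically by entity id and hull vertices are
canonicalized, so outputs are reproducible across platforms.

**Null model.** Observed FV and FOR are compared with a null in which
species identity is randomized while $N$ and $FE$ are held fixed: each
entity is guaranteed one species and the remaining $N - FE$ are assigned
uniformly at random (equal-probability multinomial), 9,999 replicates by
default. This scheme has the closed-form mean
$E[FV] = 100\,(1 - 1/FE)^{N-FE}$, which the tests use as an analytic
cross-check, and its simulated means reproduce the published null means
for the disturbance-series configurations (e.g. 15% at $N=54, FE=19$; 39%
at $N=21, FE=11$; 50% at $N=25, FE=15$). Standardized effect sizes use
unrounded null moments; p-values are empirical quantiles with the
$(r+1)/(\text{reps}+1)$ correction, two-tailed by default. A degenerate
null ($N = FE$) leaves the SES undefined and falls back to equality
counting. One published table prints a redundancy ratio of 1.90 where the
underlying $21/11 = 1.909$ rounds to 1.91 under standard rounding; the
package computes on unrounded values throughout and rounds only at
presentation.

**Multiplicity.** The adjustment method defaults to Benjamini–Hochberg
step-up applied per index and test type across all year comparisons (the
language of controlling false positives fits a false-discovery-rate
criterion), with Holm available for strict family-wise control. Both the
"each year vs. baseline" and "consecutive years" comparison families are
emitted rather than guessing which one a given annotation used; the pair
list is configurable.

## What the synthetic generator emulates

`simulate_traits()` and `simulate_cover()` generate the study conditions
the package is tested under: a 75-species pool surveyed on ten permanent
transects in six years (1981, 1983–1985, 1987, 1988) with a disturbance in
1983. Defaults were chosen once, as a realistic reef-flat scenario, and
are not tuned per analysis:

* one growth form per species, with probability 0.15 of a second (at most
  two — observed tables show at most dual membership); trait identities
  drawn from a frequency profile with branching forms frequent, massive
  most common, free-living rare. Under these defaults a 75-species pool
  realizes roughly 10–30 entities.
* log-normal baseline covers (meanlog 0, sdlog 1, percent scale),
  per-transect occupancy 0.4, gamma-distributed transect noise (shape 2):
  right-skewed covers with a few dominants, totalling a plausible
  reef-flat coral cover.
* disturbance acts multiplicatively on expected cover by response group —
  branching forms (arborescent, bushy, table) crash to 2% of baseline,
  stress-tolerant forms (massive, encrusting, column, unattached)
  transiently gain 30%, foliose is neutral — and expected covers then
  relax geometrically toward baseline at rate 0.5 per year.
* covers below a 0.05% detection limit (the centimetre-scale resolution of
  a 30 m line-intercept transect) record as zero, so a cover crash also
  removes species and entities from the recorded assemblage, as it does in
  real survey data.

The generator reproduces the *direction* of the imposed dynamics — the
branching crash and recovery, the transient stress-tolerant rise, the
entity loss and hull contraction in the disturbance year — in at least 95%
of seeds, and that is what the pipeline-level tests assert. It does not
attempt spatial structure among transects, larval connectivity, species
interactions, or realistic inter-annual autocorrelation of noise; passing
tests therefore show that the estimators recover known structure under
this data-generating process, not that any field assemblage satisfies it.

## Problem sizes and runtime choices

The test suite works at the scale the method is used at: pools of 7–75
species, 3–10 transects, up to six years; null models run at 9,999
replicates where published values are checked and a few hundred replicates
in structural tests; the direction-recovery check uses 100 seeds (40 in
the unit suite). Exact oracles (fan triangulation, brute-force quadratic
entropy, multinomial enumeration, closed-form expectations) are used
wherever a quantity has one.

## Known limitations

* Hull-based richness is two-dimensional by design; a pool whose
  morphological variation needs more axes will see FRic summarize only the
  leading plane (FDis and Q use all retained axes).
* Redundancy indices ignore abundance: a species at 0.1% cover counts as
  much redundancy as a dominant. The null model randomizes identity only,
  matching that design.
* The Gower/PCoA space depends on the species pool; adding species to the
  trait table changes coordinates, so analyses meant to be compared must
  share a pool (the package's fixed-space design enforces this within one
  analysis but not across analyses).
* Percent covers are treated as fixed observations; observation error in
  the cover estimates themselves is not propagated.
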