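---
title: "Partitioning plant trait variation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning plant trait variation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpart)
```

`traitpart` implements the computational machinery of biome-scale analyses
of plant functional trait variation: cleaning a multi-contributor trait
database by hierarchical error-risk screening, decomposing trait variance
into functional-group, species and within-species components, tracking
those components as sites are pooled across geographic scales, and
ordinating species-mean traits by principal components. Every stage can be
exercised on a synthetic database whose structure is planted and therefore
known exactly. This vignette records the statistical models, the tunable
parameters, and the design decisions taken where the methods literature
leaves choices open.

## The data model

A trait record is one measurement of one trait on one individual plant,
with taxonomic provenance (species, genus, functional group), data
provenance (a dataset identifier naming the contributing source), and
spatial provenance (a site identifier, optionally coordinates). Seven
traits are recognised: adult plant height, leaf area, seed mass, leaf mass
per area (LMA), leaf nitrogen, leaf dry matter content (LDMC), and
stem-specific density (SSD, carried only for conversion comparisons).
Trait values are strictly positive and treated as log-normal throughout:
all variance decompositions and ordinations operate on log values by
default (a natural-scale toggle exists), while the cleaning screen
operates on the natural scale, as the error-risk thresholds were
formulated for raw database values.

Records without coordinates are legal: they participate in cleaning and
variance partitioning but are excluded from spatial and climate
operations. Species temperature classes (cold / mid / warm) are the
unweighted mean of the site-level class temperature over the unique sites
where a species was collected, with strict thresholds at −1 and +1 °C;
a mean falling exactly on a threshold is "mid", and species without any
georeferenced site are flagged unclassified rather than dropped.

## Hierarchical error-risk cleaning

The *error risk* of an observation $x$ in a reference group is

$$ r(x) = \frac{\lvert x - \bar{x}_{-x} \rvert}{s_{-x}} $$

the absolute deviation from the group mean *excluding* $x$, in units of
the group's sample standard deviation. By default the standard deviation
also excludes $x$, consistent with the excluded mean; `sd_excludes_x =
FALSE` restores the full-group standard deviation. The absolute value
matters: a one-sided rule would keep low-side unit errors (values entered
in the wrong unit can be 1000× too small as easily as too large). When the
reference spread is zero the risk is 0 if $x$ equals the common value and
infinite otherwise.

Cleaning proceeds per trait, in a fixed order, each step recomputing its
statistics on the current survivors:

1. **Duplicate collapse.** Within each dataset, the ratio of duplicated
   (species, trait, value) triples is computed; datasets whose ratio
   strictly exceeds 30% have each duplicated triple collapsed to a single
   record. Datasets at or below the cutoff are untouched, because sparse
   internal duplicates are plausibly genuine repeat measurements.
2. **Global step.** Records are screened against all observations of
   their trait; risk > 8 removes the record.
3. **Dataset step.** For species present in ≥ 4 distinct datasets, a
   species mean is computed per dataset and screened against the other
   datasets' means (threshold 3.0); all of the species' records in an
   offending dataset are removed, since the flagged unit is the dataset
   mean. Species in fewer datasets are screened identically at the genus
   level with threshold 3.5.
4. **Species step.** Records are screened against their species' own
   distribution. Species with ≤ 4 records are untouched. The threshold
   grows with the record count $n$: 2.25 below 10 records, 4.0 above 30,
   linearly interpolated between (the interpolation is our choice; only
   the endpoints are fixed by the method's definition).

Reference groups too small for a step (fewer than 3 values after
exclusion) cause that step to be skipped for that group — never an error.
The output is always a subset of the input (values are never modified),
and every removal is logged with its step, risk and threshold.

Two properties are worth stating because they bound what cleaning can
achieve. First, the screen is *not* idempotent: re-running it can remove
more records as reference groups shrink. Second, it has a nonzero
false-positive rate by construction — thresholds of 2.25–4 standard
deviations applied to small, skewed (log-normal, natural-scale) groups
will occasionally flag genuine values. On the default synthetic world
(~20,000 records, 2% injected 50× outliers) the screen recovers ≈ 98% of
injected outliers while removing ≈ 1.7% of clean records; a hypothetical
clean world still loses ≈ 1–2% to these tails. Users should treat the
audit report, not a zero-removal expectation, as the check on behaviour.

## Nested variance partitioning

For one trait, the intercept-only Gaussian mixed model

$$ y_{gsi} = \mu + a_g + b_{s(g)} + e_{gsi}, \qquad
   a_g \sim N(0, \sigma^2_G),\;
   b_{s(g)} \sim N(0, \sigma^2_S),\;
   e_{gsi} \sim N(0, \sigma^2_W) $$

decomposes log trait variance into functional-group, species-within-group
and residual components; the residual is reported as the within-species
component (it also absorbs within-individual variation and measurement
error, which this design cannot separate). Components are estimated by
restricted maximum likelihood. The implementation profiles the residual
variance analytically and minimises the REML criterion over the two
variance ratios $\sigma^2_G/\sigma^2_W$ and $\sigma^2_S/\sigma^2_W$; the
likelihood is evaluated from per-species sufficient statistics (counts,
means, within-species sums of squares) in O(#species) per evaluation,
with all zero-boundary configurations evaluated explicitly, so estimates
are deterministic and components are non-negative by construction. On
balanced designs with interior solutions this REML estimator coincides
with the classical expected-mean-squares (method-of-moments) estimator,
which is also exposed (`estimator = "moments"`, with negative components
truncated at zero before normalisation); the test suite verifies both
equivalences, plus agreement with `lme4`, to tight tolerances. Degenerate
designs (a single species; one observation per species everywhere; zero
spread) return flagged decompositions with the variance assigned to the
only identifiable level rather than errors.

The model family is Gaussian with identity link on (log) values. Fractions
are the components divided by their sum and always sum to 1.

Per-site summaries apply a site filter first — by default a species needs
more than three observations of the trait at the site (read literally as
≥ 4; a configurable inclusive ≥ 3 reading exists) and a site needs at
least three qualifying species — then average the per-site fractions
*unweighted* across sites, per trait, and finally across traits. The
complementary coefficient of variation (sample SD over mean, natural
scale, per trait over all observations) summarises total variation.

## The geographic-scale accumulation scan

From each eligible start site, the scan begins with the site alone
(step 0, scale 0), then repeatedly adds the nearest not-yet-included
eligible site and refits the variance decomposition per trait on the
pooled records, until all eligible sites are included. The geographic
scale of a step is the great-circle distance (haversine, sphere radius
6371 km) from the start site to the most distant included site; measuring
candidate distances from the start site (rather than from the growing
set's hull) matches that scale definition, though a `nearest = "set"`
variant is provided. Distance ties break lexicographically by site
identifier. Site eligibility requires at least 3 species with at least 2
observations per species per trait (5/5 for sensitivity reruns, via the
same arguments). Per-step fits pool the records of all included sites
into one model rather than averaging per-site fits — pooling is what
"repartition the expanded dataset" means operationally.

At this stage exactly two sources are contrasted: *within-species*
(the residual fraction) and *among-species* (everything else, i.e.
functional-group plus species fractions folded together; a species-only
report is available).

Summaries:

* **Binning with spread intervals.** Steps are grouped into half-open
  bins (5 km or 1 species wide by convention); per bin and source the
  mean and the empirical 2.5/97.5 percentiles are reported, with bins of
  fewer than 3 steps flagged interval-undefined.
* **Ten-bin significance testing.** The axis is split into 10 equal-width
  bins — on the log10 axis by default, since scale analyses are displayed
  on a log scale; step-0 rows (scale 0) cannot be placed on a log axis and
  are excluded there — and within each bin a linear model of the
  step-level fraction on the source indicator gives a two-sided p-value
  (numerically identical to a pooled-variance two-sample t test). Bins
  with fewer than 2 steps or no variance are flagged untestable.
* **Breakpoint fits.** A continuous one-breakpoint segmented regression
  `y = a + b·x + c·(x − ψ)₊` is fitted to step-level values (not bin
  means). ψ is estimated by an exhaustive profile over admissible observed
  breakpoints — computed in O(n) via cumulative statistics after
  orthogonalising the hinge against the linear part — followed by
  continuous refinement of the profile RSS in the best bracket and an
  iterative-linearisation polish. The fit is deterministic; when the
  segmented model does not improve on a single line the fit is flagged
  non-converged and the straight-line RSS is reproduced to numerical
  precision. Case-resampling percentile bootstrap intervals for ψ are
  provided.

## Trait-space analysis

Species-mean log values (equivalently, log geometric means; all of a
species' cleaned records are pooled regardless of location, to capture
the full within-species range) form a species × trait matrix restricted
to complete cases. PCA is the SVD of the column-centred and, by default,
unit-scaled matrix — correlation form, because the six traits carry
incommensurate units; a covariance-form toggle exists. Axis signs are
arbitrary in principle, so each axis is oriented to make its
largest-magnitude loading positive, which keeps subsets and platforms
comparable (empirically, subset ordinations of the same data otherwise
flip signs). Per-axis trait contributions are $100 \cdot
\ell_{ta}^2 / \sum_t \ell_{ta}^2$ and sum to 100 by construction.
Subsets of species are placed in the full space by extracting their rows
of the score matrix, supporting per-axis range comparisons (a constrained
subset shows a range ratio below 1 on the constrained axis). An SSD→LDMC
conversion fits a log-log regression to caller-supplied calibration pairs
— the coefficients are inputs, not constants — and is intended for
supplementary comparisons only.

## The synthetic generator and what passing tests mean

The generator plants every structure the pipeline estimates. Log values
are $\mu_t + a_{g,t} + b_{s,t} + e$ with independent Normal effects per
level; species effects additionally receive $L_t \cdot z_s$ from two
standard-normal factor scores per species (a size axis and an economics
axis), so the species-level variance for trait $t$ is
`var_species[t] + rowSums(L^2)[t]` and the true fractions are known to
machine precision. Sites sit in clusters placed along one parallel with a
guaranteed inter-cluster separation and a bounded within-cluster spread
(offsets are drawn in a disc of half the nominal cluster radius);
infeasible geometries are rejected up front. Species occupy sites with
probability decaying exponentially with distance from a random home site,
which produces distance-decaying community turnover. Outliers multiply a
record's natural-scale value by a configurable factor (50× by default,
emulating unit errors); duplicates are verbatim copies within the same
dataset. All artefacts are flagged in the ground truth.

Default study conditions: 4 functional groups, 80 species, 40 sites in 4
clusters (30 km radius, 1500 km apart), 4 observations per species per
occupied site, six traits, ≈ 20,000 records, 2% outliers at 50×, 2%
duplicates. Variance components (log scale) are 0.15 / ≈ 0.30 / 0.15, i.e.
planted fractions near (0.25, 0.50, 0.25), with most of the species-level
variance carried by the two planted factors so that the first two axes of
the species-mean PCA dominate (≈ 65–75% of variance, the magnitude real
tundra ordinations show). Datasets are assigned per record from 80
parcels, emulating aggregation from many small contributors: each
species × dataset cell then holds 0–2 records, which matches what the
dataset-level screen was designed for. Assigning one dataset per site
instead makes that screen degenerate in a world with no systematic
dataset effects — whole 4-record cells are removed whenever they contain
a single injected outlier, and 4–6 dataset means have $t_2$–$t_4$ tails
against a 3.0 threshold — an artefact of granularity, not a property of
the screen.

Smaller condition sets are used where the question is structural rather
than statistical: a balanced single-site world (4 groups × 25 species ×
20 observations, planted fractions exactly (0.25, 0.50, 0.25), no factor
structure) for estimator checks; a 12-site, 3-cluster, 2-trait world for
the accumulation scan; a 120-species, weak-group world
(`var_group = 0.05`) for trait-space recovery, because strong independent
group effects act as rank-3 pseudo-factors in species-mean space and are
not part of a "two-factor" matrix. These sizes keep the full test suite
and the acceptance script within minutes on a single CPU while leaving
every estimate comfortably inside its tolerance.

What the generator does *not* emulate — and passing tests therefore do
not demonstrate — includes: systematic between-dataset offsets (lab
effects), real units heterogeneity, taxonomic synonymy, non-lognormal
trait distributions (LDMC is a bounded ratio in reality), correlation
between functional-group membership and the planted axes, spatially
autocorrelated environmental drivers of within-species variation, and the
schema of real aggregated trait databases such as TRY, the global plant
trait database. Results on real databases will differ accordingly;
in particular the local-scale rise of the within-species fraction in the
synthetic world arises from small measured species pools at small scales
(a sampling-geometry effect the scan is designed to expose), not from
environmental plasticity.

## Numerical choices

* REML optimisation: `nlminb` on log-ratios (relative tolerance 1e−14)
  plus explicit boundary candidates and a two-pass coordinate polish;
  fractions reproduce closed-form oracles to better than 1e−6.
* Zero within-species spread is detected exactly and short-circuited (the
  ratio parameterisation is unbounded there); the species means are then
  partitioned by one-way moments.
* Breakpoint search: profile over all admissible distinct x values, then
  `optimize` in the winning bracket (tolerance 1e−10 of the x range), then
  up to 10 linearisation steps accepted only when they reduce the RSS.
  Fits reproduce noiseless breaks to ≈ 1e−8.
* Percentiles use the standard interpolation definition (R type 7);
  the binning is half-open `[k·w, (k+1)·w)`.
* Duplicate detection keys on exact (dataset, species, trait, value)
  equality; no numeric tolerance, matching the "verbatim copy" semantics.
* Tie-breaks (equidistant sites) are lexicographic by site identifier,
  making scans order-invariant to input row permutations.

## Known limitations

* The dataset-level screen removes whole dataset × species cells; with
  few datasets per species its false-positive rate is governed by heavy
  t tails and can dominate the audit. Inspect the report before trusting
  aggregate removal rates on real data.
* Variance partitioning is trait-by-trait and ignores cross-trait
  covariance; within-species and measurement variance are confounded.
* The scan refits from scratch at every step; for very large site sets
  the cost grows quadratically in the number of sites per start.
* With only four functional groups the group-level fraction estimate has
  3 degrees of freedom of sampling noise (per-seed absolute errors around
  0.09 are expected even for an exact estimator); averaging over many
  sites or seeds is required before interpreting it.
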