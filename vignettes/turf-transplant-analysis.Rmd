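---
title: "Trait variation, plasticity and community convergence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait variation, plasticity and community convergence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`turftraits` implements the analysis chain used to study leaf functional
trait variation and phenotypic plasticity in reciprocal turf-transplant
experiments along elevation gradients: whole turfs (soil plus vegetation)
are moved one site down the gradient (experimental warming, about +1.5 °C)
or one site up (cooling), and leaf traits of the transplanted populations
are compared against their home populations and against the trait
composition of the community they arrive in. This vignette explains each
stage's model and assumptions, the tunable parameters, the synthetic-data
generator that backs the test suite, and the method's known limitations.

## Data model and cleaning

Trait data are long-format leaf-level observations: one row per leaf ×
trait, with taxonomy (species, genus, family, order), site, plot, block,
treatment (`wild`, `control`, `local_transplant`, `warmed`, `cooled`) and
origin site. Eleven traits are recognised: LA (cm²), LT (mm), LDMC (g/g),
SLA (cm²/g), C, N, P (%), C:N, N:P, δ¹³C and δ¹⁵N (‰). The long format
lets leaves with partial trait panels (nutrients are typically measured on
a subset) exist without sentinel values. Units are documented, never
converted: callers are responsible for supplying values on these scales.

Cleaning removes leaves whose measurements are physically or biologically
impossible: LDMC above 1 g/g (dry mass cannot exceed fresh mass), SLA
outside 5–500 cm²/g, and leaf N above 6.4 % (the highest value reported
for related genera in large trait databases). All three rules are strict
inequalities — boundary values are kept. Because LDMC and SLA both derive
from the same mass and area measurements, a violation casts doubt on the
whole leaf: cleaning therefore drops every row of an offending leaf, and
attributes the removal to the first violated rule in the fixed order
LDMC → SLA → N. Cleaning operates on original scales and must precede the
log transform. LA, LT and LDMC vary multiplicatively and are analysed on
the natural-log scale (`log_transform_multiplicative()`).

Because locally transplanted turfs were indistinguishable from untouched
controls in this design, "unmanipulated" everywhere in the package means
wild-collected leaves plus `control` and `local_transplant` plot leaves.

## Variance partitioning

`partition_variance()` decomposes trait variance across nested levels —
order, family, genus, species, population (the species × site cell) and
within-population — under the random-effects model

y = μ + b_order + b_family + b_genus + b_species + b_population + ε,

with taxonomy standing in for phylogeny. Site is nested within species
(populations), not crossed. Two estimators are provided:

* **REML** (default), via a nested random-intercept model. Field data are
  strongly unbalanced (singleton species, uneven site coverage), which
  REML handles gracefully; levels realised with a single group are
  reported as proportion 0 and flagged degenerate.
* **Moments**, a hierarchical method-of-moments on the sequential
  group-mean decomposition: at each level the mean square of group means
  around their parent means is formed, and components follow from
  differences of successive mean squares using the balanced
  expected-mean-squares identity E[MS_j] = σ²_within + Σ_{l ≥ j} m_l σ²_l
  (m_l = leaves per group at level l). On balanced designs it is unbiased
  and its components sum to the total sample variance up to O(1/n); on
  unbalanced data mean group sizes are used and REML should be preferred.
  Its independence from the REML machinery makes it the cross-check in
  the test suite.

Negative component estimates are truncated to zero *before*
normalisation, so reported proportions are nonnegative and sum to one.
Proportions are invariant to affine rescaling of the trait.

A caveat inherent to the design: species observed at a single site
confound the species and population levels; the mixed model resolves the
ambiguity by shrinkage, and the moments estimator by its nesting order.
Parameter-recovery tests compare estimates with the *pooled within-parent*
variance of the effects actually drawn by the generator — with only a
handful of orders, the draw of order effects is itself a major source of
sampling noise, and the pooled realised variance is the estimand that one
dataset can identify.

## Community trait distributions

`bootstrap_community_distribution()` builds the biomass-weighted community
trait distribution of a site by resampling: each of `B` replicates (default
1000) simulates `n_draws` individual leaves and takes their mean; the
percentile interval of the replicate means (default 95 %) accompanies
their mean.

Trait data are rarely complete, so each species' **trait pool** comes from
a fixed priority hierarchy of unmanipulated leaves: (1) the species at the
focal site, (2) the genus at the focal site, (3) the species anywhere,
(4) the genus anywhere. When a genus-level pool substitutes for a missing
species, sampling is rarefied so each congener is equally likely to be
drawn regardless of how many leaves it contributed; rarefaction applies
only to the genus rungs. Species with no pool at all are excluded and the
biomass they carry is reported as `1 - coverage` rather than silently
dropped — with realistic field data, species-level coverage of 60–85 % of
biomass is common, so this bookkeeping matters. Weights are renormalised
over covered species; biomass is pooled per site, and only relative
biomass matters.

Two numerical choices deserve explanation:

* **Deterministic proportional allocation.** Each replicate allocates its
  `n_draws` individuals across species by largest-remainder proportional
  allocation instead of multinomial draws. Species representation is then
  *exactly* biomass-proportional in every replicate: the replicate mean
  is an exactly weighted statistic, and with single-value pools every
  replicate equals the weighted community mean with a zero-width
  interval. What remains stochastic — leaf resampling within species —
  is precisely the measurement uncertainty the interval should reflect.
  Multinomial allocation would instead fold the (known) between-species
  biomass structure into the interval, inflating it by an amount
  unrelated to how well the community mean is estimated.
* **`n_draws` (default 200)** should be commensurate with the number of
  leaves actually measured at a site. Replicate means are invariant to
  `n_draws` in expectation, but interval width scales as 1/√`n_draws`;
  matching it to the observed leaf count makes the percentile interval
  approximate the sampling uncertainty of the community mean (the
  calibration test below holds 95 % intervals to 90–99 % coverage).

Percentile intervals (not BCa) are used: with mean-like statistics and
hundreds of draws per replicate the distribution of replicate means is
close to symmetric, and the percentile interval is the simplest
defensible choice. Only the mean is bootstrapped; higher moments are out
of scope.

## Relative plasticity

For each species × trait present both in a transplanted turf and in the
control-type plots of the block the turf came from, the simplified
relative distance plasticity index is

P_R = | |H − T| / H |,

where H is the mean trait value of conspecifics in the home control plots
and T the mean in the transplanted turf. Leaves are first averaged to
plot-level species means; H averages those means across the block's two
control-type plots with equal weight. The inner absolute value
standardises the direction of the shift, the outer one accommodates
negative-valued traits (δ¹³C): H = −28, T = −21 gives P_R = 0.25. P_R is
invariant to positive rescaling of the trait but *not* to additive
shifts — an intrinsic property of a ratio index, worth remembering when
comparing traits measured on interval scales. H = 0 leaves the index
undefined; such records are flagged, not dropped silently. Comparisons are
made only within blocks so that microtopographic variation does not
masquerade as plasticity.

Whether plasticity differs between warming and cooling transplants is
tested per trait by a stratified permutation test: the observed statistic
is mean(P_R | cooling) − mean(P_R | warming), and treatment labels are
permuted within species × origin-site strata, mirroring the grouping
structure under which repeated measures arise (this replaces mixed-model
t-tests with Satterthwaite degrees of freedom by an assumption-free,
exactly specified procedure; the substitution is recorded in the output
metadata). p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm), with a default of
999 permutations. Under the no-plasticity generator these p values are
uniform, which the test suite checks by Kolmogorov–Smirnov. For display,
log(P_R) is used and exact zeros are dropped with a reported count.

## Convergence and divergence

For each transplanted species × trait × turf, the turf mean T is compared
with the species' home-site summary: mean, SD and an exact central
t-interval (default 99 %) over unmanipulated leaves at the origin site.
Inside the interval the outcome is `no_change` (no significant plastic
response). Outside it, the population **converged** if it ended closer to
the destination community mean than its home mean was, and **diverged**
otherwise. Each record also carries its start group: whether the home
mean lay closer to the home or to the destination community mean before
transplantation. Community means are the biomass-weighted bootstrap means
above (an unweighted variant can be supplied for sensitivity analyses).
Ties — exactly equidistant comparisons — resolve to `home` and
`diverging` respectively; they have probability zero for continuous
traits. Outcomes are cross-tabulated (3 × 2, retaining empty cells)
against start group or against treatment, and independence is tested with
the log-likelihood ratio (G) test: G = 2 Σ O ln(O/E), with 0·ln 0 = 0,
df = (r−1)(c−1), and an upper-tail χ² p value. Keeping `no_change` as a
row gives df = 2 for the 3 × 2 tables.

## The synthetic-data generator

`simulate_dataset()` produces a complete study with known ground truth: a
balanced taxonomy; leaf values built from zero-mean Gaussian effects at
each nested level (multiplicative traits on the log scale, exponentiated);
sites in elevation order with an optional directional trend added to
population means per site step; community biomass from a symmetric
Dirichlet over species scaled to a fixed plot total; and a blocked
transplant design (per site and block: a control and a local-transplant
plot; warmed turfs originate one site up, cooled turfs one site down).
Local transplants are distributionally identical to controls, encoding
the experimental finding that transplantation itself leaves traits
unchanged.

A transplanted leaf's expectation interpolates linearly between its origin
population mean and the destination community mean:
(1 − π)·μ_origin + π·m_dest, with within-population noise; for
multiplicative traits the interpolation acts on the latent log scale. π is
set per start-distance class: species whose origin mean lies more than
one (biomass-weighted) community SD from the destination mean are `far`,
the rest `near`, with defaults π = 0.8 and 0.1 — plasticity defaults are
illustrative, as no field effect sizes exist to calibrate them. Negative π
models active divergence. The linear-interpolation mechanism is the
simplest able to produce both convergence and divergence; it encodes no
particular physiology.

Default sizes mirror the emulated field design: 4 sites about 1.5 °C
apart, 7 blocks per site, up to 5 wild leaves per species per site and 5
leaves per species per experimental plot. `site_trend` defaults to 0
because most traits show broad overlap between sites rather than
directional shifts. All outputs are pure functions of (config, seed);
per-stage sub-seeds are derived deterministically so partial regeneration
is stable. The generator emulates hierarchical trait variance, gradient
structure and plastic shifts; it deliberately omits spatial
autocorrelation, temporal dynamics, survival/mortality, trait covariance
and non-Gaussian tails, so passing tests demonstrate correctness of the
*estimators*, not realism of every feature of field data.

## Validation studies and their problem sizes

The test suite fixes these study designs (chosen for what they must
demonstrate, with all randomness seeded):

* **Variance-partition recovery**: 4 orders × 3 × 3 × 3 species, 4 sites,
  10 leaves per cell (4320 leaves), true proportions
  (0.1, 0.1, 0.2, 0.3, 0.1, 0.2); both estimators within ±0.07 of the
  realised pooled components, REML and moments within ±0.02 of each
  other, proportions summing to 1 ± 1e−9.
* **Interval calibration**: 200 datasets of 8 species × 25 leaves
  (between-species σ² = 1, within σ² = 0.25, Dirichlet α = 10), B = 1000,
  `n_draws` = 200 = the observed leaf count; 95 % intervals must cover
  the true weighted mean 90–99 % of the time.
* **End-to-end convergence study**: 16 species, 4 sites, a directional
  trend of one community SD per site step, 10 leaves per species per
  turf, one turf per population per direction, community means from
  B = 300 × 300 draws. With π = 0.8 for far species (0 otherwise) the
  outcome × start-group G-test must reject at p < 0.01 in ≥ 90 % of 50
  replicate studies; with π = 0 everywhere it must reject at α = 0.05 in
  ≤ 12 %.

The end-to-end design embodies three validity preconditions of the
classification method, each of which we found to be sharp:

1. **Communities must differ along the gradient.** With identical
   community means the home/destination dichotomy is decided by noise and
   the study question degenerates.
2. **Turf means must rest on enough leaves.** The home interval accounts
   only for home-mean uncertainty, so a noisy turf mean produces false
   "significant plasticity" far above the nominal 1 %, and populations
   starting near the destination mean then drift into "diverging" by
   regression to the mean. This artifact is worth keeping in mind when
   interpreting divergence of close starters in real data.
3. **Records entering the G-test must be independent.** Replicate turfs
   of the same population share their home mean and community means;
   with several blocks the per-turf records are pseudo-replicated and
   the G-test is anticonservative (we measured mean null G ≈ 3.5 against
   df = 2 with three blocks, against ≈ 2.1 with one turf per
   population). Field analyses that feed blocked replicates into G-tests
   inherit this inflation.

## Pipeline

`run_pipeline()` sequences the stages — load or simulate, clean,
transform, partition variance, bootstrap communities, plasticity,
convergence — writing one CSV per output family plus a JSON manifest (row
counts, seeds, config hash, package version) atomically; reruns with the
same configuration are byte-identical in numeric content. Configuration
is a YAML or R list naming exactly one of `input` (CSV paths) or
`simulate` (generator arguments); all randomness flows from the named
seeds. `turftraits_cli()` exposes the same functionality as subcommands
(`run-all`, `simulate`, `clean`, `varpart`, `bootstrap`, `plasticity`,
`convergence`) with exit codes 0 (success), 2 (configuration error) and
3 (data error).

## Limitations

* Taxonomic names are matched verbatim; no name resolution is attempted.
* Taxonomy proxies phylogeny; branch-length information is absent, so no
  phylogenetic comparative methods are offered.
* The plasticity index compares post-hoc transplant means with
  contemporaneous controls; maternal effects and epigenetic inheritance
  are indistinguishable from plasticity in this design.
* No confidence intervals on variance components, no higher bootstrap
  moments, and no survival analysis of transplants: the analysis
  conditions on survivors.
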