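---
title: "Functional diversity, species diversity and endemicity along mountain gradients: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `fdgradient`, the
assumptions behind them, the tunable parameters, and the design decisions
taken where conventions genuinely diverge in the literature. It is the
package's reference for *why* things are computed the way they are; the
README shows *how* to run them.

## The measurement model

### Mixed-type Gower dissimilarity

Species are described by eight functional traits of three kinds: five
nominal (life form, clonality, nutrient uptake strategy, leaf phenology,
dispersal strategy), one interval (flowering duration, months 1–12) and two
ordinal (floral longevity in months; spinescence, a graded 0–6 severity
scale). The pairwise dissimilarity between species $j$ and $k$ is

$$d_{jk} = \frac{\sum_i w_{ijk}\, s_{ijk}}{\sum_i w_{ijk}},$$

with all traits equally weighted. The per-trait discordance $s_{ijk}$ is 0/1
set-overlap for nominal traits, a range-normalised absolute difference for
the interval trait, and a dense-rank-normalised difference for ordinal
traits. The Boolean weight $w_{ijk}$ removes traits that carry no
information for a pair.

Four conventions had to be fixed because the classical definitions do not
cover them:

* **Multi-valued nominal traits.** A taxon may genuinely belong to more than
  one subcategory (e.g., two life forms). The equal/unequal rule is extended
  to sets: $s = 0$ if the two category sets intersect, 1 otherwise. A Jaccard
  alternative ($1 - |A \cap B| / |A \cup B|$) is available via
  `nominal_rule = "jaccard"` but off by default, because the binary rule is
  the direct extension of the single-code definition.
* **One-sided missingness.** When a trait is scored for only one member of a
  pair, $s$ is undefined. The default (`missing_rule = "classical"`) drops
  the trait ($w = 0$), the classical Gower convention. The alternative
  `"mismatch"` reads one-sided presence as information and scores $w = 1$,
  $s = 1$; it exists because a literal reading of "present in either or
  both" implies $w = 1$, and the two modes bracket the ambiguity. Structural
  missingness (leaf phenology for herbaceous taxa; flowering traits for
  gymnosperms) and unknown-but-applicable values are treated identically by
  the weights.
* **Range and rank scope.** The interval range and ordinal ranks are taken
  over the *plot's* species pool by default (`range_scope = "plot"`), making
  $d_{jk}$ plot-contextual: the same two species can be more dissimilar in a
  trait-poor community than in a trait-rich one. A `"global"` mode using the
  whole trait table is provided; per-plot is the default because the min–max
  standardisation is defined over "the sample area".
* **Zero range.** If every pool member shares one value of an
  interval/ordinal trait, the trait carries no discriminating information:
  $s = 0$, weight unchanged (no information, no penalty).

A pair sharing *no* applicable trait cannot be scored and raises an error
naming the pair — no silent imputation.

### Diversity metrics

Functional diversity is Rao's quadratic entropy over the full ordered double
sum,

$$\mathrm{FD} = \sum_{i=1}^{S}\sum_{j=1}^{S} p_i\, p_j\, d_{ij},$$

with $p_i$ the relative cover-code abundance (raw code divided by the plot's
code total; the 1–9 ordinal cover-abundance codes are used as abundance
surrogates without back-transformation to percent cover). When all
inter-species dissimilarities equal 1, FD reduces to Gini–Simpson
($1 - \sum p_i^2$), which is the sense in which Rao's Q generalises Simpson
diversity. Because a functionally redundant species dilutes abundance
without adding trait distance, FD can decrease while richness increases —
the package asserts this on a constructed example.

Species diversity is Shannon–Wiener, $H' = -\sum p_i \ln p_i$ (natural log
by default; bases 2 and 10 are options since the convention is
software-dependent). Endemicity is the fraction of a plot's taxa flagged
endemic; a cover-weighted variant ($\sum p_i$ over endemics) is reported
alongside when requested, because a per-plot endemicity metric has no single
standard definition.

### Sampling adequacy

The first-order jackknife estimate is
$S^*_j = S_{obs} + Q_1 (Q - 1) / Q$, where $Q$ is the number of plots and
$Q_1$ the number of species occurring in exactly one plot — the standard
Heltshe–Forrester "uniques" definition. (Loose verbal restatements of $Q_1$
as "the number of species in a given plot" circulate; they contradict the
estimator's derivation and are not used.) A network is adequately sampled
when $S_{obs}/S^*_j$ reaches 80% by default.

## Stratification and descriptive statistics

Vegetation belts are half-open 500-m elevation bands, lower-inclusive:
[0, 500) Thermo-, [500, 1000) Meso-, [1000, 1500) Supra-, [1500, 2000) Oro-,
[2000, ∞) Cryoro-Mediterranean. TPI groups partition the real line at the
belt-mean-derived cutpoints with right-closed intervals:
(−∞, −377], (−377, −198], (−198, −32], (−32, 146], (146, ∞). Printed
integer bounds (−376, −197, −31, +147) would leave unit gaps on a continuous
scale; the half-open convention restores totality, and both classifiers are
tested to be total and monotone.

Group comparisons use one-way ANOVA with Tukey HSD post hoc by default;
Games–Howell (pairwise Welch $t$ referred to the studentized range) is the
unequal-variance alternative, since the original post hoc procedure is a
matter of software defaults rather than a stated choice. Degenerate input in
which every observation is identical returns $F = 0$, $p = 1$ rather than
0/0. Min–max scaling (`scale_metrics()`) maps each metric to [0, 1] across
plots for comparable box plots; constant columns map to zeros.

## The model-comparison harness

Eleven regression families are compared: MLR, PLSR, ridge, regression tree,
MARS, GAM, beta regression, quantile regression at $\tau = 0.5$ and
$0.75$, Huber, and MM-estimation. Standard fitters are used where installed
(lm, `MASS::lm.ridge` with GCV, `rpart`, `mgcv`, `MASS::rlm`,
`glmmTMB` with a beta family); PLS1 (NIPALS with internal 5-fold component
selection), a degree-1 MARS (forward hinge selection, GCV pruning with
penalty 3), and quantile regression by iteratively reweighted least squares
on the check loss are implemented in the package.

Conventions, chosen once and applied uniformly:

* **Information criteria.** For least-squares-like families
  $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k+1)$ and
  $\mathrm{AICc} = \mathrm{AIC} + 2(k+1)(k+2)/(n-k-2)$, with $k$ the
  effective parameter count (coefficients; leaves for trees; basis terms for
  MARS; trace-based edf for ridge; summed edf for GAM). Quantile regression
  uses the check-loss analogue; beta regression its exact likelihood.
* **Cross-validation aggregation.** Per repeat, plots are randomly
  partitioned into 10 folds; held-out predictions are pooled within the
  repeat, metrics computed on the pool, then averaged over repeats. The
  reported test RMSE is the square root of the averaged test MSE, so
  $\mathrm{RMSE}^2 = \mathrm{MSE}$ holds on every report row. Training
  metrics come from the full-data fit.
* **$R^2$.** Out-of-sample $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, so an
  uninformative model scores at or below zero. Quantile families report the
  check-loss pseudo-$R^2$ against the intercept-only quantile.
* **Best model.** Highest test $R^2$, ties broken by lower test AICc. A
  family that fails to fit is recorded as a failed row, never a fatal error.
* **Variable selection.** Greedy stepwise (forward with drop steps) or
  backward search minimising the family's AIC; AIC ties break towards the
  lexicographically smaller variable subset so selection is deterministic.
* **Beta regression support.** When the response touches 0 or 1, the
  standard squeeze $(y(n-1) + 0.5)/n$ is applied.

Exact numeric replication of any particular published metric table is out of
scope: repeated unseeded cross-validation and fitter internals make those
numbers software-specific. The harness is validated by its properties
instead — the invariants above, an oracle predictor scoring perfectly,
known-noise RMSE recovery, and GAM outranking MLR on nonlinear truths.

## The final GAM

The interpretation models are additive cubic regression splines at fixed
target df (`mgcv` with `fx = TRUE`), e.g. FD on s(elevation, df = 4) +
s(TPI, df = 4) and SD on s(elevation, df = 5) + s(slope, df = 5). Fixed df
(rather than penalised smoothness selection) keeps the ANOVA decomposition
exact: with two df-4 smooths and 136 plots the residual df is
$136 - 1 - 8 = 127$.

The ANOVA table has two blocks. The *parametric* block tests each term's
linear part: sequential least-squares sums of squares referred to the full
GAM's residual mean square on $F(1, \mathrm{df}_{res})$. The
*nonparametric* block tests each smooth against its linear restriction:
$F = [(\mathrm{RSS}_{lin} - \mathrm{RSS}_{full})/(\mathrm{df}-1)] /
\mathrm{MS}_{res}$ on $F(\mathrm{df}-1, \mathrm{df}_{res})$. Partial-effect
curves are mean-centred with pointwise standard-error bands, and the
intercept plus the term contributions reconstruct the fitted values to
numerical precision. Grid prediction clamps covariates outside the training
range to the range edges and flags those cells as extrapolated rather than
silently extrapolating a spline.

## The synthetic community generator

The generator exists so every stage of the pipeline can be exercised, and
its recovery tested against known truth, without field data. Its defaults
encode the study conditions the analysis assumes: 136 plots spanning
54–3070 m split 27/26/26/21/36 across the five belts with the published
per-belt habitat-type quotas; a pool of 1017 taxa with exactly 174 endemics
(endemism probability rising with the elevation optimum, drawn as a weighted
sample without replacement); belt mean TPI pinned exactly to −198 / −377 /
−31 / +146 / +184 by centring the within-belt residuals (a
conditional-simulation choice: the belt means are observed study statistics,
the within-belt spread is simulated); and an expected 5505 occurrence
records.

Assembly is deliberately the simplest mechanism that produces the expected
gradients: Gaussian elevation niches
$\exp(-(e - \mu_s)^2 / 2\sigma^2)$ thinned to a target expected richness
profile, cover codes from a rank-based quantile mapping of a lognormal
latent abundance onto a decreasing nine-code distribution, and *trait
convergence* — high-elevation specialists sampled from restricted
trait-category subsets (chamaephyte/hemicryptophyte-heavy, clonal, spiny,
short-flowering) with probability scaling in the strength parameter
$\theta$ (default 0.8, ramping in over 800–2000 m so the imposed FD decline
matches the expected partial-effect shape: rise to ~800 m, decline to
2000 m, flat above). The expected-richness profile follows the non-monotone
species-diversity trend the analysis expects (low-elevation peak, dip near
1000 m, secondary rise near the tree line, alpine decline); setting
`sd_trend = FALSE` flattens it. Every species left undrawn by the niche
model is recorded once at its best-matching plot, reflecting that the pool
*is* the recorded flora.

Two lessons from the recovery tests are worth recording. First, Rao's Q is
abundance-based, so any richness/evenness gradient leaks weakly into FD even
with elevation-independent traits; second, niche sorting makes each random
pool induce its own smooth trait-composition gradient along elevation, so
per-seed significance tests of "no FD trend" are anti-conservative under the
full study-shaped configuration. The $\theta = 0$ null test therefore uses
the ceteris-paribus design — flat richness profile, wide niches — which
isolates the convergence mechanism; at study-shaped defaults the generator
*intends* a FD–elevation trend and the tests assert its sign and ordering
instead.

What the generator does **not** emulate: spatial autocorrelation and
dispersal (plots are exchangeable given elevation), real trait covariance
structure (traits are conditionally independent given the convergence
regime), bedrock/climate effects on occurrence (bioclim columns are smooth
elevation surrogates for schema and selection testing only), and observation
error in cover coding. Passing recovery tests therefore show the *pipeline*
recovers imposed structure — not that real communities assemble this way.

## Problem sizes used by the tests and scripts

The packaged test-suite and the acceptance script run the full 136-plot /
1017-taxon configuration for the dataset-level checks (a complete diversity
table takes about two seconds), reduced configurations (60 plots,
250–500 species) for the 50-seed recovery suites, 20 seeds for the GAM vs
MLR ranking, 50 for the partial-effect shape, and 1000 replicates for the
ANOVA null uniformity check; the harness comparison uses 10-fold
cross-validation with 5 repeats. These sizes were chosen so each suite
completes in minutes while keeping Monte-Carlo error well inside the
asserted margins.

## Known limitations

* The per-plot endemicity metric has no canonical definition; both variants
  are provided, and correlation magnitudes against other metrics depend
  on the choice (signs do not, in our simulations).
* Quantile regression by IRLS approximates the exact linear-programming
  solution; adequate for harness ranking, not for boundary-exact quantile
  inference.
* The degree-1 MARS omits interaction terms by design.
* Plot-contextual Gower means FD values are not comparable across plot
  networks with different pools; use `range_scope = "global"` when
  cross-network comparability matters more than within-plot contrast.
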