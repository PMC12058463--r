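# fdgradient

Quantifying how plant **functional diversity (FD)**, **species diversity
(SD)** and **endemicity** vary with elevation and topography in
Mediterranean mountain vegetation plots — for community ecologists working
with plot networks of cover-abundance records and categorical trait tables.

The package implements the full quantitative pipeline:

* **Mixed-type Gower dissimilarity** between co-occurring species over eight
  vegetative and regenerative traits (nominal, possibly multi-valued;
  interval; ordinal), with structural missingness handled by Boolean
  weights:
  `d_jk = Σᵢ w_ijk s_ijk / Σᵢ w_ijk`
* **Rao's quadratic entropy** as the FD metric,
  `FD = Σᵢ Σⱼ pᵢ pⱼ d_ij` (full ordered double sum; reduces to
  Gini–Simpson when all d = 1), **Shannon–Wiener** `H′ = −Σ pᵢ ln pᵢ` as
  alpha SD, and per-plot **endemicity** (fraction of taxa flagged endemic),
  all from 1–9 cover-abundance codes.
* **First-order jackknife** sampling adequacy,
  `S*ⱼ = S_obs + Q₁ (Q − 1)/Q`, with the 80% adequacy criterion.
* **Stratification** into the five Mediterranean vegetation belts (500-m
  bands) and five TPI groups, with Pearson correlations, one-way ANOVA and
  Tukey/Games–Howell post hoc comparisons, and min–max scaled summaries.
* A **model-comparison harness**: AIC-based variable selection and repeated
  10-fold cross-validation over eleven regression families (MLR, PLSR,
  ridge, regression tree, MARS, GAM, beta, two quantile regressions, Huber,
  MM), reporting R², MAE, MSE, RMSE, AIC and AICc for training and test.
* **Fixed-df GAMs** (cubic regression splines, e.g. `FD ~ s(elevation, df=4)
  + s(TPI, df=4)`) with a two-block ANOVA table (parametric and
  nonparametric effects), mean-centred partial-effect curves with standard
  errors, and clamped grid prediction.
* A **synthetic community generator** reproducing the statistical shape of a
  136-plot / 1017-taxon mountain study (belt quotas, habitat quotas, belt
  mean TPI, endemism rising with elevation, trait convergence at high
  elevation) with recorded ground truth for recovery tests.

See `vignettes/diversity-gradients.Rmd` for the methods and the design
decisions, and `analysis/01_simulate.R` … `analysis/05_gam.R` for the
step-by-step workflow (each writes its tables under `results/`).

## Worked example

```r
library(fdgradient)

fx  <- end_to_end_fixture(sim_config(seed = 1))   # traits, plots, env, truth
div <- diversity_table(fx$plots, fx$traits, fx$env)

sampling_adequacy(fx$plots)$ratio      # 0.946  (>= 0.8: adequately sampled)
pearson(div$endemicity, div$fd_rao)    # r = -0.59, p = 4.4e-14, n = 136

fit <- fit_gam(div$fd_rao, c(elevation = 4, tpi = 4),
               data.frame(elevation = div$elevation, tpi = div$tpi))
gam_anova(fit)$nonparametric
#>                  term npar_df       f         p
#>  s(elevation, df = 4)       3 13.2160 1.453e-07
#>        s(tpi, df = 4)       3  0.7385 5.310e-01
```

Running the workflow scripts on the same seed prints, among other things:

```
seed 1: 136 plots, 1017 recorded taxa (174 endemic), 5571 records
jackknife: S_obs = 1017, S_jack = 1074.6, adequacy = 94.6% (>= 80%: TRUE)
endemicity-FD r = -0.589 (p < 1e-13), endemicity-SD r = -0.526, FD-SD r = 0.240
Best family by test R2 (AICc tie-break): GAM
FD elevation partial effect declines over 800-2000 m: TRUE
```

Read: the synthetic plot network is adequately sampled by the jackknife
criterion; endemicity is negatively associated with both diversity metrics
while FD and SD are only weakly related; the GAM outperforms the other ten
families out of sample; and the fitted elevation effect on FD declines
between 800 and 2000 m, the imposed habitat-filtering signal.

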