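---
title: "Methods: size diversity and biomass trophic transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size diversity and biomass trophic transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizetransfer)
```

This vignette documents the models and numerical choices behind
`sizetransfer`: what each stage computes, which knobs matter, what the
synthetic survey does and does not emulate, and where the design was
genuinely open.

## From two axes to carbon

Imaging instruments report, per individual, the major and minor axes of
the enclosing ellipse. Only two axes are measured, so the third must be
assumed: we take the individual as a prolate spheroid with the two short
semi-axes equal, giving `EllipVol = (π/6)·M·m²`. For a sphere (M = m)
this is the usual `(π/6)d³`; for elongated mesozooplankton it avoids the
systematic distortion an equivalent-spherical-diameter treatment would
introduce.

The per-sample processing order is fixed and pinned by tests: carnivore
filter → shrinkage correction → biomass conversion → aggregation.
Shrinkage (a multiplier on prey cell volume, compensating preservation
losses) and the power-law biomass conversion `factor·V^exponent` commute
only when the exponent is 1, so the order is semantically meaningful:
shrinkage acts on *volume*, conversion afterwards. The default
conversion table (factor 1, exponent 1, shrinkage 1) is deliberately a
placeholder that reproduces volumetric scaling and warns when used;
absolute biomass interpretation requires group- (or taxon-) specific
literature factors, which the table accepts.

## Size diversity

The diversity statistic is the differential entropy

$$\mu = -\int p_x(x)\, \log p_x(x)\, dx, \qquad x = \log(\mathrm{EllipVol}),$$

with \(p_x\) estimated by a weighted Gaussian kernel density. Log
transformation puts organisms spanning ~10 orders of magnitude in volume
on a scale where a single bandwidth is meaningful.

Numerical choices, each with a convergence or invariance guard in the
test suite:

* **Weights.** Abundance weights are normalized once
  (\(\tilde w_i = w_i/\sum w\)) and everything downstream uses only
  \(\tilde w\). Consequently µ is *exactly* invariant to rescaling all
  weights — the "mathematically independent from total biomass" property
  holds at floating-point resolution, not merely approximately. Tied
  log-sizes are aggregated (weights summed) and the support is sorted
  before estimation, so listing every individual twice, or permuting
  the rows, leaves µ bit-identical.
* **Bandwidth.** Silverman's rule by default,
  \(h = 0.9\,\min(s, \mathrm{IQR}/1.34)\, n_{\mathrm{eff}}^{-1/5}\),
  evaluated on the weighted sample with the Kish effective size
  \(n_{\mathrm{eff}} = 1/\sum \tilde w_i^2\); Scott's rule and a fixed
  bandwidth are available (the fixed mode is also the only way to get a
  defined—if degenerate—answer for a zero-spread sample). No canonical
  bandwidth rule is established for this statistic, so it is exposed as
  an option rather than hard-coded.
* **Integration.** Trapezoid rule on a 1024-point uniform grid extending
  4 bandwidths past the data range (Gaussian mass beyond that is below
  1e-4). Tests require halving or doubling the grid to move µ by less
  than 1e-3.
* **Bases.** Natural log for both the size transform and the entropy
  (µ in nats) by default; base-10 size transform and base-2 entropy are
  options. Either choice shifts µ by a constant, so all comparisons in
  one analysis must share a base — the package never mixes them.

Against the closed form \(\tfrac12\ln(2\pi e \sigma^2)\) for normal
log-sizes, the KDE estimate carries a small positive smoothing bias
(variance inflated by ~\(h^2\)); at \(n = 5\times10^4\) the error is
well inside 0.05 nats, and it shrinks with \(n\) (tested at
\(10^3, 10^4, 5\times10^4\)).

## Transfer metrics

`log10(PPBR)` — predator over prey total biomass — is the transfer
proxy; it is antisymmetric under exchanging the groups and undefined
(an error naming the sample) when either biomass is non-positive, e.g.
after the carnivore filter empties a predator collection. The direct
estimate `log10(PPPR)` uses production \(P = gB\) with the
artificial-cohort growth rate \(g = \ln(W_t/W_0)/\Delta t\); negative
growth is retained with a warning rather than truncated, because mass
loss over an incubation is informative, not impossible. PPMR (the
predator–prey individual mass ratio) uses abundance-weighted *geometric*
means per group — the natural average for a log-scale size variable; the
averaging convention is a package choice, stated here because other
conventions (arithmetic means, medians) exist in the literature.

Proxy uncertainty is propagated by nonparametric case resampling of
samples (not individuals — the sample is the exchangeable unit), 1000
replicates and percentile intervals by default. The bootstrap accepts a
refit hook so that the selected mixed model is refitted on every
resample; the report states the fraction of resamples in which each
coefficient keeps its full-data sign. At the validation-subset scale
(n ≈ 29) percentile intervals for a strong correlation are mildly
anti-conservative; the package's coverage test documents the achieved
rate (≥ 0.90 at nominal 95%) rather than pretending exactness.

## Environmental covariates

"Depth-integrated" nutrients are depth-weighted *mean* concentrations
(µM): the trapezoidal integral from the shallowest bottle to the mixed
layer depth divided by the span, interpolating to the MLD when the cast
extends deeper. A mean (rather than an areal stock in mmol m⁻²) keeps
the covariate on the concentration scale, commensurate with surface
values in regressions. Nutrients enter models as natural logs; zeros
engage an offset equal to the smallest positive observation, loudly
reported, since detection limits are survey-specific.

## Mixed models and model selection

All models are station random-intercept LMMs (via `nlme::lme`) fitted by
**maximum likelihood**, because AICc comparisons across different
fixed-effect structures are invalid under REML. The AICc parameter count
is `fixed effects (incl. intercept) + 2` variance components.

The denominator df convention is containment:
\(df = n_{\mathrm{obs}} - n_{\mathrm{stations}} - n_{\mathrm{slopes}}\),
so a 106-sample, 40-station survey gives 65 df for a univariate model
against 105 for the ungrouped baseline. Wald t statistics are referred
to this df; p-values are reported but never used for selection.

Degenerate designs collapse explicitly rather than failing obscurely: a
single grouping unit, or a boundary fit (zero residual or random
variance), falls back to ordinary least squares with a warning — which
is also the correct limit, and the tests require the t statistics to
agree with ordinary regression to 1e-6 there.

All-subsets selection enumerates every admissible subset of the
candidate terms under marginality (an interaction only with both main
effects; {A, B, A:B} yields 5 models including the intercept-only one),
refuses more than 20 terms, and ranks by AICc with ties broken by fewer
parameters then input order.

## The synthetic survey

The generator's defaults are the study conditions of the package:

* 40 stations × 3 samples (the survey scale the methods target — about a
  hundred samples over tens of stations; an equal-allocation design is
  used for simplicity);
* 3500 prey and 2000 predator individuals measured per sample;
* log-biovolume drawn from two-component normal mixtures
  (prey 0.6·N(5.5, 1.2²) + 0.4·N(8.5, 1.5²), predators
  0.7·N(16.5, 1.2²) + 0.3·N(19, 1.5²), natural-log µm³), right-skewed
  and bimodal on the volume scale as real communities are, and chosen to
  place prey in the nano-micro range and predators in the
  mesozooplankton range;
* aspect ratios log-uniform in [1, 1.5] for prey and [2, 6] for
  predators (near-spherical cells, elongated zooplankton); axes are
  back-computed from the drawn volume so the morphometry round-trips
  exactly;
* a station-level random shift (sd 0.3) on log-biovolume means, giving
  the station structure the random intercept is meant to absorb;
* surface covariates drawn multivariate-normal with a warm-oligotrophic
  correlation pattern, linear-with-depth nutrient profiles, and
  *diversity links* — configurable slopes that scale the size-mixture
  spread with standardized covariates (defaults: prey spread shrinks
  with SST, predator spread shrinks with silicate) so that
  environment–diversity relationships of known sign exist to recover;
* integer abundance weights (1 + Poisson(3)): particle counts per m³
  are integers, and exactly representable weights make the
  biomass-independence invariance testable bit-exactly;
* carnivore flags on a configurable fraction of predators — synthetic
  metadata for testing the filter, standing in for taxonomic screening.

What the generator does *not* emulate: taxonomy, plankton behaviour,
food-web dynamics, spatial autocorrelation beyond the station effect,
instrument segmentation error, or any particular sea's hydrography.
Passing recovery tests therefore demonstrates that the estimators and
the selection machinery are correct and well calibrated under known
structure — not that any ecological conclusion transfers to a given
survey.

The companion mixed-model generator (`simulate_lmm_dataset`) defaults to
106 observations over 40 stations with a slope of −1.655 — a realistic
effect size for a size-diversity covariate — random-intercept sd 0.3 and
residual sd 0.4, and is the surface on which parameter recovery
(estimates within 3 SE of truth in ≥ 95% of replicates) and selection
consistency (a strong generating interaction recovered in ≥ 90% of
replicates; intercept-only winning a plurality under pure noise) are
tested. Test problem sizes (100 replicates; 200 coverage replications
with 500 bootstrap resamples) keep the suite comfortably fast while
leaving the stochastic margins wide.

## Reproducibility plumbing

One seed governs a pipeline run; the simulation and the bootstrap
consume derived streams (`seed`, `seed + 1`, `seed + 2`), so stages are
independently reproducible. Every output CSV begins with comment lines
embedding the MD5 hash of the configuration and the seed; a rerun with
the same configuration is byte-identical, which the tests assert.

## Known limitations

* The bandwidth rule and entropy base are conventions; µ values are
  comparable only within a fixed choice of both.
* The containment df rule is one of several defensible conventions for
  mixed-model Wald tests (Satterthwaite and Kenward–Roger being the
  common alternatives); it is simple, matches the survey arithmetic, and
  is applied uniformly — including to the intercept.
* Biomass conversion defaults are placeholders; absolute biomasses and
  hence the *level* (not the structure) of log10(PPBR) are arbitrary
  until real factors are configured.
* The production-ratio validation subset is simulated around shared
  biomasses, so its proxy correlation is favourable by construction; it
  exercises the machinery, not the ecological claim.
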