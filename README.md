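# sizetransfer

Does the size structure of plankton communities shape how efficiently
biomass moves up the food web? `sizetransfer` is an R package and analysis
workflow for studying that question with survey data of individually
measured plankton: nano-microplankton *prey* imaged by flow cytometry and
mesozooplankton *predators* (carnivores excluded) from net tows, sampled
repeatedly across stations. It is aimed at quantitative plankton
ecologists who have per-individual size measurements and want a tested,
reproducible path from raw particle tables to mixed-model inference.

## The quantities at the core

- **Ellipsoidal biovolume.** Each individual's major (M) and minor (m)
  ellipse axes give a prolate-spheroid volume
  `EllipVol = (π/6)·M·m²` (µm³) — preferable to the equivalent spherical
  diameter for elongated zooplankton. Prey volumes are corrected for
  preservation shrinkage; carbon biomass follows a configurable power law
  `factor · V^exponent` per group.
- **Size diversity µ.** The Shannon-analogue diversity of the individual
  size distribution: `µ = −∫ pₓ(x) log pₓ(x) dx`, the differential
  entropy of a weighted Gaussian kernel density estimate on
  `x = log(EllipVol)`. Because it is built from relative contributions,
  µ is mathematically independent of total biomass (the package tests
  this invariance bit-exactly).
- **Trophic transfer proxy.** `log10(PPBR)`, the log10 ratio of predator
  to prey total biomass, validated against the production-rate ratio
  `log10(PPPR)` (growth rates by the artificial-cohort method,
  `g = ln(W_t/W_0)/Δt`), with uncertainty propagated by case-resampling
  bootstrap.
- **Inference.** Station random-intercept linear mixed models fitted by
  maximum likelihood, with containment denominator df
  (`n − stations − slopes`; 106 observations over 40 stations with one
  covariate give df = 65). Single predictors are ranked by AICc; the
  most parsimonious model is found by exhaustive all-subsets selection
  with marginality enforced for the prey × predator diversity
  interaction.

Because surveys of this kind are rarely redistributable, the package
ships a synthetic survey generator with known size mixtures, known
regression structure and known random-effect variance, so that every
stage has a parameter-recovery test surface.

## Worked example

```r
library(sizetransfer)

# a small synthetic survey: 6 stations x 2 samples
samples <- simulate_individuals(community_sim_config(
  n_stations = 6, samples_per_station = 2,
  n_prey_individuals = 300, n_predator_individuals = 200, seed = 11))

conv <- biomass_conversion_table(
  prey = list(factor = 1e-8, exponent = 0.9),
  predator = list(factor = 5e-9, exponent = 0.95),
  shrinkage_factor = 1.33)

tab <- summarize_samples(samples, conv)
head(tab[, c("sample_id", "log10_ppbr", "prey_mu", "predator_mu")])
#>   sample_id log10_ppbr  prey_mu predator_mu
#> 1   st01_s1   3.976909 2.098142    2.067870
#> 2   st01_s2   3.983860 1.946070    2.005927
#> 3   st02_s1   3.813812 2.030614    1.895852
#> ...

fit_lmm("log10_ppbr", c("prey_mu", "predator_mu"), "station_id", tab)
```

Each summary row holds one sample's biomasses, the transfer proxy, prey
and predator size diversity (nats), mass- and diversity-ratio covariates,
and environmental predictors (depth-integrated nutrients above the mixed
layer, log-transformed).

## The analysis workflow

The numbered drivers under `analysis/` run the full study on the
synthetic survey (40 stations × 3 samples; 3500 prey and 2000 predator
individuals per sample), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_survey.R    # particle + environment tables
Rscript analysis/02_sample_summaries.R   # per-sample analysis rows
Rscript analysis/03_univariate_ranking.R # AICc ranking of single predictors
Rscript analysis/04_model_selection.R    # all-subsets AICc selection
Rscript analysis/05_bootstrap_proxy.R    # PPPR validation + bootstrap
```

On the default seed the workflow prints, among others:

```
cor(prey_mu, log10 PPBR): r = -0.74, p = 2.2e-22, n = 120
cor(predator_mu, log10 PPBR): r = 0.82, p = 1.5e-30, n = 120
Most parsimonious model: log10_ppbr ~ prey_mu + predator_mu + prey_mu:predator_mu + ln_sio3 (AICc -357.00)
log10(PPBR) vs log10(PPPR): r = 0.82, 95% CI [0.69, 0.91] (n = 29)
```

i.e. prey size diversity depresses and predator size diversity promotes
the biomass transfer proxy in the generated communities, the selected
model retains their interaction, and the proxy correlates strongly with
the direct production-ratio estimate on the validation subset — the
qualitative structure the generator encodes, recovered end to end.

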