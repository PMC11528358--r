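# sisage

Simulation and inference tools for a question from behavioural disease
ecology: **does becoming less socially connected in old age protect
against infectious disease?** In many group-living animals, ageing
individuals keep fewer and weaker social ties at the same time as their
immune systems decline. `sisage` quantifies how much of the age gradient
in infection burden is carried by that social change, by simulating an
endemic pathogen over behavioural-observation networks and contrasting
mixed-model age coefficients with and without social-centrality
covariates.

## What it does

* **Synthetic observation data** (`gen_config()`, `generate_study()`):
  group-years of individuals (age, focal-sampling effort) and dyadic
  grooming-bout counts, with a tunable age–sociality coupling so the
  downstream estimate can be validated by parameter recovery. Real data in
  the same two-table layout can be read with `read_group_year()`.
* **Uncertainty-aware networks** (`fit_edge_posterior()`,
  `draw_networks()`): a conjugate Bayesian count edge model per dyad —
  grooming rate `w ~ Gamma(0.1 + bouts, 0.1 + focal_i + focal_j)` — and
  posterior draws of whole weighted networks, so sampling uncertainty
  propagates into everything downstream.
* **Centrality** (`centrality_table()`): strength (summed edge weights),
  weighted closeness (inverse mean shortest-path length with edge length
  `1/w`) and degree thresholded at the group-year's minimum observed
  non-zero weight.
* **SIS epidemics** (`run_sis()`, `run_experiment()`): discrete-time
  stochastic susceptible–infected–susceptible dynamics with per-edge
  transmission probability `(si + ai) * w^0.7`, infection duration
  `di + adi` steps and per-step cost `ci + aci`, where `ai`, `adi`, `aci`
  rise linearly with age (anchors 6 and 28 years) when the corresponding
  immunosenescence switch is on. The design grid (`parameter_grid()`)
  crosses three transmissibilities (0.45 / 0.60 / 0.75) with the three
  switches: 24 parameterizations. The core loop is C++ (Rcpp).
* **Inference** (`build_frame()`, `fit_cost_models()`,
  `protective_effect()`, `age_contrast()`): Gaussian mixed models of
  accumulated infection cost with random intercepts for group-year,
  individual and group-year × simulation. Model 1 is `cost ~ age`; model 2
  adds the three centralities as 5-level within-group-year z-score
  categories; model 3 interacts each with age. The **protective effect of
  social ageing** is the model-1 age estimate minus the model-2 age
  estimate — negative values mean age-related declines in centrality
  buffer infection cost. Costs convert to baseline-infection equivalents
  via `cost_to_infections()` (one baseline infection = `di * ci` = 5 cost
  units).

`run_pipeline()` composes the whole chain and returns an object with
`print`, `summary`, `coef` and `plot` methods. See the vignette
(`vignettes/social-ageing-epidemics.Rmd`) for the model details and design
rationale.

## Worked example

Five synthetic group-years with the default (calibrated) social-ageing
coupling, 50 posterior networks each, high-transmissibility control
epidemic (no immunosenescence):

```r
library(sisage)
cfg <- gen_config(n_group_years = 5, rng_seed = 42)
ex <- run_pipeline(cfg, n_draws = 50,
                   grid = parameter_grid(si = 0.75, controls_only = TRUE))
summary(ex)
#> Social-ageing epidemic experiment: 5 group-years x 50 draws x 1 parameterizations (250 runs)
#> Mean centrality: strength 0.139, closeness 0.0078, degree 4.35
#> Protective effect of social ageing (model 1 - model 2 age estimates):
#>              param_id beta_age_m1 beta_age_m2 protective_effect pe_se
#>  si0.75_ai0_adi0_aci0       -1.12      -0.314            -0.806 0.318
#>
#> Model-3 high-to-average contrasts (cost change, young = 8 y, old = 18 y):
#>              param_id strength_young strength_old closeness_young closeness_old
#>  si0.75_ai0_adi0_aci0          -12.4        -12.6           -5.96         -5.15
#>  degree_young degree_old
#>         -5.57      -6.41
```

Reading: each year of age lowers accumulated infection cost by 1.12 cost
units when social position is ignored (model 1) but only 0.31 units once
degree, strength and closeness are held fixed (model 2). The difference,
−0.81 cost units per year — about 0.16 baseline infections per year
(`cost_to_infections(-0.806)`) — is the protective effect of social
ageing: most of the apparent age decline in infection cost is explained by
older individuals' lower social centrality. The model-3 contrasts give the
predicted cost change of having `average` rather than `high` centrality at
ages 8 vs 18 (negative = cost reduction).

A thin command-line wrapper is provided:

```sh
Rscript scripts/run_pipeline.R --group-years 5 --draws 50 --grid control \
    --si 0.75 --steps 500 --seed 42 --out results/demo
Rscript scripts/run_pipeline.R --validate   # worked-example arithmetic checks
```

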