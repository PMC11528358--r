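---
title: "Quantifying the protective effect of social ageing against endemic disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the protective effect of social ageing against endemic disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

In many group-living animals, individuals become less socially connected as
they age: fewer grooming partners, weaker ties, a more peripheral network
position. Whatever its proximate causes, this "social ageing" changes an old
individual's exposure to directly transmitted pathogens at exactly the life
stage when immune function declines (immunosenescence). `sisage` implements
a simulation-and-summary pipeline that asks: **how much of the age gradient
in infection burden is attributable to age-related differences in social
network position?**

The pipeline has five stages, each usable on its own:

1. **Observation data** — per group-year tables of individuals (id, age,
   focal-sample count) and undirected dyadic grooming-bout counts; either
   user-supplied (`read_group_year()`) or synthetic (`generate_study()`).
2. **Edge model** — a conjugate Bayesian count model of grooming rates per
   dyad (`fit_edge_posterior()`), from which whole weighted networks are
   sampled (`draw_networks()`), propagating sampling uncertainty.
3. **Centrality** — strength, weighted closeness and thresholded degree per
   individual per posterior draw (`centrality_table()`).
4. **Epidemic simulation** — a discrete-time stochastic SIS process on each
   draw, with optional linear immunosenescence in susceptibility, infection
   duration and severity (`run_sis()`, `run_experiment()`).
5. **Inference** — three Gaussian mixed models of accumulated infection
   cost, whose age coefficients define the *protective effect of social
   ageing* (`build_frame()`, `fit_cost_models()`, `protective_effect()`).

`run_pipeline()` composes all five and returns a classed experiment object
with `print`, `summary`, `coef` and `plot` methods.

## The edge model and why uncertainty is propagated

For a dyad observed grooming $x$ times while its two members were focal
subjects $d = f_i + f_j$ times in total, the observed edge weight is the
rate $x/d$. Two dyads with rates $1/2$ and $100/200$ have the same point
estimate but very different certainty. We therefore model the latent
grooming rate $w_{ij}$ with a gamma prior (default
$\mathrm{Gamma}(0.1, 0.1)$, weakly informative) and the conjugate count
update

$$ w_{ij} \mid x, d \;\sim\; \mathrm{Gamma}(0.1 + x,\; 0.1 + d), $$

independently across dyads. Every unordered pair — including pairs never
seen grooming — retains strictly positive posterior support, so each
posterior draw is a complete weighted graph. Downstream quantities are
computed per draw and averaged by the mixed models, so edge-weight
uncertainty flows into the final coefficients rather than being collapsed
early. The study-scale design uses 1000 draws per group-year.

Hyperparameters are exposed; the prior's influence is a rate of
$0.1/(0.1+d) \approx 10^{-3}$ on never-observed dyads at typical effort,
small against observed rates of order $10^{-2}$.

## Centrality definitions

* **Strength**: sum of incident edge weights (total grooming rate).
* **Closeness**: the inverse of the mean weighted shortest-path length to
  all other individuals. Weights are rates, so an edge of weight $w$ is
  given length $1/w$ — the standard rate-to-distance transform; paths are
  computed on the complete draw (igraph's Dijkstra).
* **Degree**: number of incident edges with weight at or above the
  group-year's *minimum observed non-zero weight*. Posterior draws put
  (tiny) positive weight on every dyad, so an unthresholded count would be
  $n-1$ for everyone; thresholding at the weakest empirically observed tie
  keeps the weakest real connections — which old females lose first — while
  discarding posterior mass on never-observed dyads. A weight exactly equal
  to the threshold is counted.

Closeness and strength are computed on the complete draw; only degree is
thresholded.

## The SIS simulator

Each individual is susceptible (S) or infected (I); a dormant recovered
state exists in the code but its duration `dr` is 0 throughout the
analysis, so recovery returns individuals directly to S and re-infection is
immediately possible (endemic dynamics). Time is discrete; the analysis
horizon is 500 steps (a step is naturally read as a day). Per step, each
susceptible $i$ runs one independent Bernoulli trial against every
step-start infected neighbour $j$, with success probability

$$ P_{j \to i} = \min\{1,\; (s_i + a_i)\, A_{ij}^{0.7}\}, $$

where $s_i \in \{0.45, 0.60, 0.75\}$ is the baseline transmissibility
(chosen so equilibrium prevalence corresponds to $R_0 \approx 1$–$3$ via
$R_0 = 1/(1-\text{prevalence})$), $a_i$ is the age increment to
susceptibility, and the exponent $0.7 \in (0,1]$ up-weights weak ties.
The product can exceed 1 for strong edges, hence the clamp. Updates are
synchronous against the step-start infected set, and durations are
decremented after transmission, so an individual recovering at step $t$
cannot transmit at $t+1$.

An infection lasts $d_i + adi$ steps and accrues $c_i + aci$ cost units per
infected step; with baselines $d_i = 5$, $c_i = 1$ a control infection
costs exactly 5 units. Age effects scale linearly between global anchors 6
and 28 years (the study's age range; global rather than per-group anchors
for cross-group comparability): at age $a$,
$f(a) = \mathrm{clamp}((a-6)/22, 0, 1)$ and

* susceptibility: $a_i = 0.25 f(a)$ when on (so the oldest-to-youngest
  transmission ratio at $s_i = 0.45$ is $0.70/0.45 = 1.56$),
* duration: $adi = \mathrm{round}(10 f(a))$ — always a whole number of
  steps, giving durations 5–15,
* severity: $aci = 2 f(a)$, giving per-step costs 1–3.

The factorial design crosses the three on/off switches with the three
transmissibilities: 24 parameterizations, of which 3 are controls. At the
study scale (23 group-years × 1000 draws × 24 cells) this is 552,000 runs;
`run_experiment()` streams results to disk for that reason. The simulator
core is a small C++ loop (Rcpp) driven by R's RNG, so runs are reproducible
under derived seeds and the full acceptance designs execute in seconds.

Choices the simulator makes where a convention was needed:

* **Seeding**: 10% of individuals (at least one) are infected uniformly at
  random at step 0. This reliably reaches the endemic regime without a
  burn-in, and no burn-in is discarded — accumulated cost is counted over
  the whole run. Both are exposed (`init_infected`, `n_steps`).
* **Trial granularity**: one Bernoulli trial per infected neighbour, the
  event-level reading of "each interaction"; a combined
  $1-\prod(1-p)$ draw is equivalent in distribution.
* **Equilibrium prevalence** for the $R_0$ approximation is the mean over
  the final 100 steps.
* Infections ongoing at the horizon accrue only the steps served; the event
  log records assigned and served durations so cost conservation is
  checkable exactly.

## The mixed models and the protective effect

Per parameterization, accumulated cost is analysed with Gaussian linear
mixed models carrying random intercepts for group-year, individual id and
group-year × simulation:

* **Model 1**: `cost ~ age` — the raw age gradient, inclusive of any
  age-related variation in network position.
* **Model 2**: `cost ~ age + degree + strength + closeness` — the age
  gradient net of social position. Centralities enter as 5-level ordered
  categories from within-group-year z-scores (`very_low` < −1.5 ≤ `low` <
  −0.5 ≤ `average` < 0.5 ≤ `high` < 1.5 ≤ `very_high`; lower bounds
  inclusive, reference level `average`). Binning follows the analysis
  convention of the source data; z-scoring is within group-year, pooled
  across draws, and uses each simulation's own draw-specific centralities.
* **Model 3**: `cost ~ age * (each category)` — how centrality effects
  change with age, summarized as the predicted cost change of moving from
  `high` to `average` centrality at 8 years (young; lower data quartile)
  versus 18 years (old; median age of death for females reaching
  adulthood), read off the fixed effects. An `average`-to-`low` variant is
  available as a robustness check.

The **protective effect of social ageing** is the model-1 age estimate
minus the model-2 age estimate. Negative values mean part of the apparent
age decline in infection cost is carried by age-related centrality
differences. Because the two estimates come from separate fits of the same
data, their sampling covariance is not available; the reported uncertainty
`pe_se` is the independence bound $\sqrt{se_1^2 + se_2^2}$, used only for
calibration checks, not hypothesis tests (the analysis is descriptive, and
effect sizes are the target). Cost differences convert to
baseline-infection equivalents by dividing by $d_i c_i = 5$.

Numerical notes: fits use `lme4::lmer` (REML); singular variance
components are reported and the fit retained; random intercepts with a
single observed level (possible in toy runs) are dropped with a message;
category levels absent from a frame are dropped before fitting.

## The synthetic generator

The generator emulates the statistical structure of an intensively sampled
female primate population without reproducing any real group's data:

* group sizes ~ rounded normal(51, 14) truncated to 19–73;
* ages from a truncated geometric on 6–28 (decay ratio 0.8532, solved so
  the mean is 11.2, right-skewed like a natural age pyramid);
* focal counts uniform on 25–50 per individual;
* latent gregariousness
  $g_i = \exp(\alpha - \rho\,(\text{age}_i - 6) + \varepsilon_i)$ with
  $\varepsilon_i \sim N(0, 0.4^2)$;
* dyadic bout counts Poisson with mean $g_i g_j (f_i + f_j)$ times mean-one
  log-normal noise (sd 0.3), matching the conjugate count model downstream
  and keeping overdispersion tunable.

$\rho$ (`age_decline_rate`) is the social-ageing dial: 0 gives
age-independent sociality in expectation (the null used for calibration
tests), and the expected slope of log-gregariousness on age is exactly
$-\rho$, so the coupling is recoverable by Poisson regression of
individual bout totals on age. Defaults were frozen from pilot
simulations (~2000 individuals): $\alpha = -3.113$ puts mean per-network
bout totals near 169 with ≥90% of networks in 33–392, and $\rho = 0.027$
puts the pooled age–strength correlation near −0.13, the weak negative
coupling typical of empirical reports.

What the generator does *not* emulate: kinship and matriline structure,
community modularity, directed grooming, demographic turnover, and the
absolute scale of empirical centrality summaries. On the last point, the
published summaries of comparable field data (mean strength ≈ 0.6 alongside
~169 bouts per ~51-female network and minimum non-zero weights of
0.008–0.027) are not jointly attainable under the weight definition
bouts/(focal$_i$+focal$_j$): with ~169 bouts spread over ~1300 dyads at
those denominators, mean strength is necessarily ~0.15. The generator
prioritizes bout totals, group sizes, ages, minimum-weight range and the
age–centrality correlation; synthetic strength/closeness/degree therefore
sit on a somewhat different absolute scale, which is immaterial for the
protective-effect analysis because centralities enter the models as
within-group z-score categories. Consequently, passing tests validate the
pipeline's logic and calibration on data with this structure — they do not
certify empirical coefficient values on any real population.

## Problem sizes used by the test-suite experiments

Calibration and recovery experiments in the package's tests use 5 synthetic
group-years × 50 posterior draws × the high-transmissibility control cell
(250 runs of 500 steps, ~12,000 model rows), a size at which one experiment
completes in a few seconds while leaving the protective-effect estimate
well resolved: under the null ($\rho = 0$) it is within 2 SE of zero, and
under the default coupling it is negative in ≥9 of 10 replicate
experiments. The simulator itself is validated against an exact oracle: on
a two-node network the first-infection time is geometric with parameter
$(s_i) A^{0.7}$, checked by a χ² goodness-of-fit test on 10⁴ replicates.

## Known limitations

* Dyads are independent in the edge model (no zero-inflation, no dyadic
  covariance, no directed edges), as in an edge-wise conjugate model.
* Behaviour does not respond to infection: no sickness-induced withdrawal
  or care-giving feedbacks; the contact network is fixed within a run.
* The recovered state is dormant by design (`dr = 0`); SIR/SEIR dynamics
  are out of scope.
* Whether the denominator of the within-model count likelihood should be
  pair-specific joint observation effort rather than the sum of the two
  individuals' focal counts is unresolved in the field; the sum is adopted
  here to match the observed-weight definition.
* The protective-effect SE is an independence bound (see above).
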