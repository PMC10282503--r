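---
title: "Hierarchical community CJS models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical community CJS models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cjscommunity)
```

This vignette documents the statistical model implemented by
`fit_cjs_community()`, the assumptions behind every stage of the pipeline,
the numerical choices made where the design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The estimation problem

Mist-netting stations band individual birds and re-encounter some of them
in later years. Because detection is imperfect, the fraction of birds seen
again confounds three things: mortality, permanent emigration, and failure
to detect a bird that is present. The Cormack–Jolly–Seber (CJS) model
separates *apparent survival* $\phi$ (survive **and** return to the study
area) from *recapture probability* $p$ by conditioning on first capture
and modelling the pattern of re-encounters. Apparent survival always
confounds mortality with permanent emigration; nothing in this package
removes that confounding.

The package targets a community setting: several species captured at one
station over $T$ annual breeding seasons, with interest in (a) species- and
age-specific survival, (b) community-level relationships between survival
and species traits (migratory behavior, body size), and (c) species-level
relationships between annual survival and climate.

## From banding records to m-arrays

Records are collapsed to one detection per bird per breeding season. A
season spanning the year boundary (September–March) is labelled by its
starting year, so "occasion $t$" is the season that begins in September of
year $t$; annual survival is then defined between consecutive breeding
seasons. Birds aged as juveniles anywhere within their first season are
juvenile releases (conflicting codes resolve to juvenile, and the
resolution is logged); unknown-age birds are treated as adults. Netting
sites are merged: any site column is ignored.

Species enter the analysis only when at least 50 individuals were captured
and at least 4 individuals were recaptured in a later season — counted at
the individual level, not the event level. A species carries a juvenile
age class only when at least 25 individuals were first captured as
juveniles (`min_juv_releases`); below that the juvenile releases are
excluded and only adult survival is estimated for that species.

Capture histories are summarized as age-structured m-arrays: for each
species and release age class, `m[i, j]` counts birds released at occasion
`i` and *first* re-encountered at occasion `j`, plus a never-re-encountered
cell. The m-array is the sufficient statistic of the CJS likelihood, so
the marginalized multinomial likelihood over m-array rows is exactly
equivalent to the individual state-space formulation as long as there are
no individual covariates — which is the case here, where covariates vary
by year and species only. Year-level residuals survive this
marginalization unchanged. The m-array route is orders of magnitude faster
and is testable against exhaustive per-individual enumeration, which the
test suite does at tolerance `1e-10`.

Transients are not modelled: restricting data to the breeding season is
the design defence against them, and the goodness-of-fit suite (below)
checks whether a transient signal remains.

## Covariates

Survival over the interval between occasions $t$ and $t+1$ is regressed on
the nonbreeding (austral winter) conditions inside that interval:

* **temp** — mean daily minimum temperature (°C) over April 1–August 31;
* **precip** — summed daily precipitation (mm) over the same window;
* **ENSO** — mean monthly multivariate ENSO index from April through the
  following March (nonbreeding season through the end of the subsequent
  breeding season);
* **year** — the interval index, as a continuous trend term.

Recapture probability at occasion $t$ is regressed on that season's catch
effort (net-hours × net area). All continuous covariates are centered and
scaled to sample SD 1, which makes slope magnitudes comparable and gives
the ROPE rule below a single natural width. Pairwise Pearson correlations
among temp, precip and ENSO are computed and any $|r| \ge 0.5$ raises a
structured warning (configurable to a hard failure); the fit proceeds,
because the gate is a data-quality alarm, not a model assumption.

Small gaps in the daily weather series are filled by linear interpolation
in time and the fill count is logged. This is a deliberate, documented
substitute for reanalysis-based infilling, which needs gridded products
and is out of scope; for gap fractions up to ~20% of a window the
interpolation error is negligible relative to between-year variance.
A window missing entirely is a hard error naming the year.

Each covariate series is also tested for a temporal trend by OLS on the
occasion index with a two-sided t-test. Trend reports cover all three
climate covariates; the package deliberately reports all three rather than
singling one out.

## The hierarchical model

For species $s$, age class $a \in \{\text{juv}, \text{ad}\}$ and interval
$t$:

$$\text{logit}\,\phi_{t,s}^{a} = \alpha_s^a + \beta_{1,s}^a\,\text{year}_t
  + \beta_{2,s}^a\,\text{temp}_t + \beta_{3,s}^a\,\text{precip}_t
  + \beta_{4,s}^a\,\text{ENSO}_t + \varepsilon_{t,s}^a,
  \qquad \varepsilon_{t,s}^a \sim N(0, \sigma_s^a)$$

$$\text{logit}\,p_{t,s} = \alpha_s^p + \beta_{1,s}^p\,\text{effort}_t
  + \varepsilon_{t,s}^p$$

Recapture is shared across age classes. The community level ties the
species intercepts together and carries the trait regression:

$$\alpha_s^a \sim N\!\left(\mu^a + \beta_{MB}^a\,MB_s + \beta_{BS}^a\,BS_s,\;
  \sigma_\mu^a\right), \qquad \alpha_s^p \sim N(\mu^p, \sigma_\mu^p)$$

with $MB_s$ a 0/1 migrant flag and $BS_s$ the standardized mean adult body
mass. Trait slopes are estimated separately per age class.

**Priors.** Inverse-logit of each community hyper-mean is Uniform(0, 1)
(equivalently, a standard logistic density on the logit scale, Jacobian
included). Every regression slope is Normal(0, variance 10) — i.e.
precision 0.1 in the BUGS convention. All SDs (hyper-SDs and temporal
residual SDs) are Uniform(0, 10), a standard weakly-informative choice for
logit-scale scales; the upper bound is far above any plausible logit-scale
SD and its exact value is immaterial in practice.

**Intercept convention.** The species-level regression reuses the species
intercept $\alpha_s^a$ drawn from the community distribution. A
`literal_intercepts` switch instead uses the community mean $\mu^a$
directly as every species' intercept and drops the hierarchy — the
non-hierarchical form one obtains by reading the species-level regression
equations in isolation. The hierarchical form is the default because it is
the only reading under which the species-level normal distributions have a
role; the switch exists so the literal form can be reproduced and compared.

**Residual vector lengths.** Survival residuals have length $T-1$ (one per
interval). Recapture residuals also have length $T-1$, indexed by
occasions $2..T$: recapture at the first occasion is not a parameter of a
CJS model conditioned on first release, so a $T$-length vector would carry
one permanently unidentified entry.

## Sampling

The posterior is sampled by componentwise adaptive random-walk Metropolis
(Metropolis-within-Gibbs). Per-coordinate log step sizes adapt toward an
acceptance rate of 0.44 by Robbins–Monro updates during burn-in and are
frozen afterwards, keeping the post-burn-in chain a valid fixed kernel.
The same kernel exists twice:

* `run_mcmc()` — a generic R implementation over any log-posterior
  function. This is the pluggable sampler contract; it is what the
  conjugate-toy calibration tests exercise.
* a compiled implementation specialized to this model, used by
  `fit_cjs_community()`. It caches per-species linear predictors, rates,
  log-rates and likelihood contributions, so a parameter update only
  recomputes the slice it touches. The compiled log-posterior is
  cross-checked against the pure-R `hierarchical_logprior()` +
  `marray_loglik()` path in the test suite (agreement to ~1e-9 on random
  parameter vectors).

Internally the compiled sampler uses the non-centered parameterization of
the temporal residuals ($\varepsilon = \sigma z$, $z \sim N(0,1)$), which
mixes far better than the centered form when the per-year data are weak —
the usual situation for species with low recapture rates. Draws are
reported on the centered ($\varepsilon$) scale, so the parameterization is
an implementation detail invisible to the user.

Numerical choices: cell probabilities that underflow are floored at
`log(1e-300)` and counted; incremental cache updates are rebuilt exactly
from the parameters on rejection, and fully refreshed every 100 sweeps to
bound floating-point drift; chain $c$ is seeded with `seed + c - 1`, and a
given seed/configuration reproduces draws bit-for-bit. Initial values are
drawn near crude data-based estimates (recapture fractions for $p$,
moderate survival otherwise) with jitter; initialization retries until the
log-posterior is finite.

Two MCMC profiles are built in: the production profile (3 chains ×
110,000 iterations, 10,000 burn-in, thinned by 5 → 60,000 kept draws) and
a scaled-down profile for simulation studies and routine checking
(3 × 6,000, burn-in 2,000, thinned by 2 → 6,000 kept draws). The
parameter-recovery study in the test suite runs 20 replicate fits at the
scaled-down profile; that size keeps the whole study at a few minutes on
one CPU while leaving Monte-Carlo error well below the widths of the
intervals being checked.

Convergence is judged by the classic Gelman–Rubin $\widehat{R}$ from
between- and within-chain variances, with 1.1 as the flag threshold;
degenerate (zero-variance) chains are reported as unconverged rather than
assigned a number. The split-chain variant is not used, matching the
classic diagnostic's definition; structural parameters (everything except
the year-level residuals) are the headline set reported in the run
manifest.

## Effect indices

For every slope the package reports the posterior mean, an equal-tailed
credible interval (89% by default; 95% also available, and both appear in
the rate table), and three existence/significance indices:

* **pd** — probability of direction: $100 \cdot \max(\Pr(\beta > 0),
  \Pr(\beta < 0))$, between 50 and 100. Draws exactly at zero count toward
  neither sign and are logged.
* **HDI** — the shortest interval containing $\lceil 0.89 n \rceil$ sorted
  draws; ties go to the earliest window. The sample-based definition (no
  density smoothing) is deterministic and brute-force verifiable.
* **% in ROPE** — the percentage of the HDI's draws inside
  $[-0.1, +0.1]$. Because all predictors are standardized, $\pm 0.1$ on
  the logit-scale slope is the natural "practically zero" region; the
  stated rule ("0.1 × SD of the response") is ambiguous for a
  binary-outcome logit model, and the scaled-predictor reading is taken as
  operative. The half-width is configurable. Categories: `< 1%` in ROPE →
  significant; `< 2.5%` → probably significant; `100%` (ROPE covers the
  HDI) → null-accepted; otherwise undecided. Computing the percentage over
  HDI draws (not all draws) follows the convention of the Bayesian-indices
  literature; a switch selects the all-draws variant.

## Goodness of fit

The GOF suite works on each species' pooled-age capture histories and
follows the classical sequential factorization of the capture-history
multinomial, so the per-occasion contingency tables are quasi-independent
under the null CJS model and their chi-squared statistics sum to an
asymptotic chi-squared on the summed degrees of freedom:

* **3.SR (transience)** — at each occasion, newly vs previously marked
  animals × ever re-encountered afterwards or not.
* **3.Sm (re-encounter timing)** — among animals re-encountered later,
  newly vs previously marked × occasion of next encounter. (Some sources
  label this component 2.Sm; it is the same construction.)
* **2.CT (immediate trap-dependence)** — detection at $i$ × detection at
  $i+1$ among animals seen at-or-before $i$ and at-or-after $i+1$. Signed
  per-occasion $z$ statistics are reported as a supplement (positive =
  trap-happiness).
* **2.CL (timing dependence)** — among animals seen at-or-before $i$, not
  at $i+1$, and again later, detection at $i$ × occasion of next
  encounter.

Pooling rule: within a table, columns are merged (rightmost offender into
its left neighbour) until every expected count reaches 2; tables that
cannot reach that are skipped and contribute no degrees of freedom. No
continuity correction is applied. The overall test sums the four
components. The null calibration of all four components is verified by
simulation in the test suite: 500 datasets from a constant-rate CJS null
(cohorts of 80 new releases over 12 occasions, $\phi = 0.65$, $p = 0.35$ —
sizes chosen so every component has usable tables), with the rejection
rate at $\alpha = 0.05$ required to sit within three binomial standard
errors of 0.05. No overdispersion correction (ĉ) is fed back into the
Bayesian fit.

## The synthetic-data generator

`sim_scenario()` defines a complete study; `simulate_environment()` and
`simulate_histories()` (or `simulate_study()`, which also writes the CSV
files) realize it. The default scenario emulates the motivating study
design: five species over 20 occasions, with per-species newly-banded
totals equal to the published per-species capture counts (323/474,
375/676, 0/136, 0/73, 772/780 juveniles/adults; together 3,609 new
individuals — the age-class capture columns sum slightly above the
printed total of banded individuals, and the generator follows the
per-species columns), true mean rates at the published posterior means,
exactly one migrant species, and planted climate effects only on that
migrant's juvenile survival: precipitation slope 1.45 and ENSO slope
−1.60 on the logit scale. All other slopes are zero, so the recovery
study can check both detection of real effects and the absence of false
ones. Residual SDs default to 0.3 on the logit scale — moderate year-to-year
noise typical of passerine survival series.

The environment generator produces daily minimum temperature (annual mean
5°C, seasonal amplitude 4.5°C — warmest mid-January, coldest mid-July — a
planted linear trend of 0.10 °C/year, and Gaussian daily noise with SD
2°C), log-normal daily precipitation (meanlog −0.3, sdlog 1.2: ≈ 555 mm/yr,
matching a wet sub-Antarctic station), a stationary AR(1) monthly ENSO
index (autocorrelation 0.85, innovation SD 0.3), and log-normal annual
effort. The seasonal cycle uses a fixed 365-day calendar (Feb 29 mapped to
Feb 28) so that a noiseless planted trend aggregates to an exactly linear
winter series — a property the tests exploit.

Records are emitted as dated breeding-season handling events (one to three
per detected season, so within-season collapsing is exercised), with a
configurable fraction (default 10%) of adult first captures recoded to
age "unknown" — only adults are recoded, so the unknown→adult rule never
creates a mismatch between the generator's ground truth and the ingested
data. A ground-truth sidecar (true parameters, true rates, true m-arrays,
true histories) is always available, giving every downstream module an
oracle; the test suite checks that ingesting the emitted records
reproduces the truth m-arrays cell for cell.

What the generator does **not** emulate: transients, within-season
(robust-design) structure, site effects, age misclassification of
juveniles, density dependence, and observation-driven effort feedback
(effort is exogenous). Passing the recovery tests therefore shows that the
estimator inverts its own generative assumptions at realistic sample
sizes — not that real data satisfy those assumptions; the GOF suite is the
check on the latter.

## Pipeline and reproducibility

`run_pipeline()` chains ingest → filter → m-arrays → covariates → GOF →
fit → effect indices → reports, writing plain CSV/JSON artifacts (rate
table with 89% and 95% intervals and C/R count columns, effect-index
table, GOF and trend reports, per-occasion covariates, serialized
m-arrays, and a machine-readable manifest with the seed, draw counts,
maximum structural $\widehat{R}$ and any unconverged parameters — an
unconverged run completes but warns prominently). Configuration comes from
a single `pipeline_config()` object, optionally read from YAML with
explicit arguments overriding the file. Reruns with the same seed write
byte-identical tables. The package is a library rather than a shell tool:
the configuration object plus `run_pipeline()` is the entry point, and
`scripts/acceptance.R` shows the end-to-end invocation.

## Known limitations

* Apparent survival confounds mortality and permanent emigration;
  juvenile estimates are particularly sensitive to natal dispersal.
* The final-interval $\phi_{T-1} p_T$ product is only weakly separable, a
  generic CJS identifiability limit; hierarchical shrinkage stabilizes but
  does not remove it.
* With five species the trait regression has five observations per age
  class; its slopes are reported with full posteriors but cannot be
  expected to reach significance under the ROPE rule.
* The componentwise sampler mixes slowly for strongly correlated slope
  pairs (e.g. a year trend term alongside a trending climate covariate);
  the manifest's $\widehat{R}$ report is the guard.
* The collinearity gate checks climate covariates pairwise; it does not
  gate the year term against a trending covariate.
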