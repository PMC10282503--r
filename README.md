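# cjscommunity

Hierarchical multispecies Cormack–Jolly–Seber (CJS) survival analysis for
long-term banding studies, built around the kind of question a 20-year
mist-netting series raises: how do annual apparent survival and recapture
probability vary across the species of a community and its age classes,
and are the year-to-year swings in survival associated with winter
weather and broad-scale climate?

The package takes raw banding records (band id, species, date, age code,
body mass), daily weather, a monthly multivariate ENSO index, and annual
catch effort, and carries them through capture-history construction,
species filtering, age-structured m-arrays, goodness-of-fit testing, a
Bayesian hierarchical two-age-class CJS model, and posterior effect
indices. A synthetic-study generator with a full ground-truth sidecar
makes every stage testable without any real data.

## The model

For species $s$, age class $a \in \{\mathrm{juv}, \mathrm{ad}\}$ and
interval $t$ between breeding seasons:

```
logit φ[t,s,a] = α[s,a] + β1[s,a]·year_t + β2[s,a]·temp_t
                 + β3[s,a]·precip_t + β4[s,a]·ENSO_t + ε[t,s,a]
logit p[t,s]   = α[s,p] + β5[s]·effort_t + ε[t,s,p]
```

with `ε ~ N(0, σ[s,a])` year-level residuals, recapture shared across age
classes, and a community level tying species together:

```
α[s,a] ~ N(μ[a] + βMB[a]·MB_s + βBS[a]·BS_s, σμ[a]),   α[s,p] ~ N(μ[p], σμ[p])
```

where `MB` is a migrant/resident flag and `BS` standardized mean adult
body mass. Individuals first captured as juveniles use juvenile survival
for their first interval and adult survival afterwards; unknown-age birds
are adults. Priors: Uniform(0,1) on the inverse-logit hyper-means,
Normal(0, variance 10) on all slopes (precision 0.1), Uniform(0,10) on all
SDs. The likelihood is the marginalized m-array multinomial, sampled by
adaptive Metropolis-within-Gibbs in compiled code; effects are summarized
with the probability of direction (pd), 89% highest-density intervals,
and the percentage of the HDI inside a ±0.1 region of practical
equivalence (ROPE), with `<1%` → significant, `<2.5%` → probably
significant, HDI fully inside the ROPE → null accepted.

Goodness of fit follows the U-CARE component suite on each species'
histories: transience (3.SR), re-encounter timing (3.Sm), immediate
trap-dependence (2.CT) and timing dependence (2.CL), summed into an
overall chi-squared test.

## Worked example

Simulate the default five-species, 20-season study and run the whole
pipeline (the scaled-down MCMC profile; `mcmc_profile = "full"` selects
the production profile of 3 × 110,000 iterations):

```r
library(cjscommunity)

config <- pipeline_config(scenario = sim_scenario(),
                          mcmc_profile = "test", seed = 1)
res <- run_pipeline(config)
print(res$fit)
```

```
Hierarchical two-age-class CJS community model
  5 species, 20 occasions (2001-2020), 320 parameters
  6000 kept draws (3 chains x 6000 iterations, burn-in 2000, thin 2)
  max R-hat (structural parameters): 1.077

Posterior mean rates (89% CI):
      species           phi_juv            phi_ad                 p
      elaenia 0.45 (0.32, 0.57) 0.68 (0.63, 0.74) 0.09 (0.07, 0.12)
   house_wren                   0.53 (0.38, 0.67) 0.09 (0.04, 0.19)
     rayadito 0.38 (0.28, 0.49) 0.45 (0.40, 0.49) 0.34 (0.28, 0.40)
 sierra_finch 0.31 (0.20, 0.44) 0.39 (0.32, 0.46) 0.13 (0.09, 0.17)
       thrush                   0.49 (0.31, 0.64) 0.27 (0.13, 0.49)
```

Each row is a species' posterior mean rate with its 89% credible
interval: `phi_juv`/`phi_ad` are juvenile and adult apparent annual
survival (blank where too few juveniles were banded to support a juvenile
age class) and `p` is recapture probability. The generator plants climate
effects only on the migrant's juvenile survival (precipitation +1.45,
ENSO −1.60 on the logit scale); the effect indices recover them:

```r
subset(res$effects, species == "elaenia" & age == "juv",
       c(covariate, mean, lower, upper, pd, pct_in_rope, category))
```

```
 covariate   mean  lower  upper   pd pct_in_rope             category
      year  0.283 -3.582  4.012 55.0        4.44            undecided
      temp -0.154 -3.597  3.326 51.8        4.66            undecided
    precip  2.230 -0.181  4.857 93.3        1.57 probably significant
      enso -3.105 -6.425 -0.741 98.6        0.00          significant
```

The two planted slopes surface with pd ≈ 93% and 99% and small ROPE
fractions, while the planted-zero year and temperature slopes stay
undecided with pd near 50%. `res$trends` recovers the planted winter
temperature trend (0.097 °C/yr against a true 0.10, p ≈ 3e-12),
`res$gof` shows no significant lack of fit on data simulated from the
model itself, and `res$rate_table`, written with both 89% and 95%
intervals and C/R count columns, is the publication-style table.

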