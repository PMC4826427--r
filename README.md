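# t1dapc

Cancer incidence in a type 1 diabetes cohort versus the general
population, modelled with smooth age–period–cohort (APC) Poisson rate
models on exactly split person-time — plus a synthetic-registry
generator with known ground truth that makes the whole pipeline
verifiable.

## The scientific problem

National diabetes registers in Australia, Denmark, Finland, Scotland
and Sweden follow people diagnosed with type 1 diabetes before age 40
and link them to cancer registries.  Does this cohort experience more
cancer than the general population, and how does any excess vary with
*duration of diabetes*?  The shape of the duration profile is the
scientific crux: a spike of cancer diagnoses in the first year after
diabetes onset is the signature of ascertainment bias (entering
medical care means more examinations, which find more cancers), while
a persistent long-duration excess would suggest a real biological
effect.

Register data cannot be redistributed, so the package pairs the
analysis machinery with a piecewise-exponential registry simulator
whose hazard ratios are known exactly.  Every stage — simulation,
Lexis splitting, tabulation, model fitting — is tested against that
ground truth and against closed-form oracles.

## The model

For a Lexis cell with age $a$, period $p$, cohort $c = p - a$ and
duration band $d$ (general population = reference level), events are
Poisson with

```
log λ = f_n(a) + g_n(p) + h_n(c) + δ_d ,     offset log(person-years)
```

where `f_n, g_n, h_n` are per-country natural cubic splines with
case-balanced knots and `exp(δ_d)` is the hazard ratio versus the
general population — a smooth generalisation of the classical
standardised incidence ratio (`smr()`), to which it reduces exactly on
a single stratum.  The exact APC collinearity is resolved by
detrending one spline basis (person-years-weighted projection onto
{1, x} removed); `δ` is invariant to which basis is constrained.
Duration enters as bands cut at 0, 1, 2, 5, 10, 15 and 30 years since
diagnosis, with an explicit `"unknown"` level for prevalent cases
without a recorded diagnosis date.

## A worked example

Simulate a Finnish male cohort of 100,000 with the default declining
duration profile (true hazard ratios 2.3, 1.2, 1.1, 1.05, 1, 1, 1 over
the seven bands), split and tabulate the follow-up, and fit the
duration model:

```r
library(t1dapc)

cfg <- sim_config(n = 100000, countries = "FI", sexes = c(M = 1))
eff <- list(all = default_true_effect("all"))
reg <- simulate_registry(cfg, eff, seed = 2)

seg <- split_follow_up(reg$cohort, windows = cfg$windows)
rt  <- rate_table(tabulate_lexis(seg), reg$population, site = "all")

fit <- apcfit(rt, diabetes = "duration")
print(fit)
```

```
Age-period-cohort Poisson rate model (diabetes-duration contrasts)
  15858 cells, 432268 events, deviance 9215.62 on 15833 df
  Hazard ratios vs general population:
    level    hr  lo95 hi95 se_log
   dur0-1 2.596 1.843 3.66 0.1748
   dur1-2 1.447 0.933 2.25 0.2240
   dur2-5 1.282 1.000 1.64 0.1267
  dur5-10 1.081 0.906 1.29 0.0905
 dur10-15 1.002 0.863 1.16 0.0763
 dur15-30 0.971 0.916 1.03 0.0298
   dur30+ 0.989 0.963 1.02 0.0141
```

The fitted first-year hazard ratio 2.60 (95% CI 1.84–3.66) recovers
the true 2.3 and declines to 1 across the bands — while the overall
binary contrast and the classical ratio see essentially nothing:

```r
hr_table(apcfit(rt, diabetes = "binary"))
#>   level    hr lo95 hi95 se_log
#> 1   t1d 0.994 0.97 1.02 0.0125
smr(rt)
#> [1] 0.993
```

which is precisely why the duration decomposition matters: a first-year
ascertainment spike is invisible in the aggregate.

`plot(fit)` draws the hazard-ratio-by-duration profile on a log scale;
`run_pipeline()` runs the whole chain for a multi-site, two-sex demo
configuration and writes a reproducible CSV/JSON/figure bundle with a
digest manifest.  A thin command-line wrapper lives in
`inst/cli/t1dapc` (subcommands `simulate`, `split`, `fit`, `report`,
`check-table1`).

The package also ships, as plain CSV fixtures, a published
five-country summary table of cohort cancer counts and person-years;
`table1_checks()` recomputes every margin and derived percentage and
flags the (two) rows that are inconsistent as printed.

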