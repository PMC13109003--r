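# separisk

Separable versus controlled direct effects with competing events: tools for
quantifying what goes wrong when an analysis "censors by competing events"
although the causal question is about a separable direct effect.

## The problem

In trials with competing events (e.g. estrogen therapy vs. placebo for
prostate cancer mortality, where cardiovascular death precludes the
outcome), the default analysis treats competing events as censoring. At
best that targets a **controlled direct effect**,

    CDE0 = Pr(Y^{a=1, d=0} = 1) − Pr(Y^{a=0, d=0} = 1),

the effect in a hypothetical world where competing events are eliminated.
An investigator who actually wants the effect of the treatment component
acting on the event of interest — a **separable direct effect**,

    SDE0^{aD} = Pr(Y^{aY=1, aD} = 1) − Pr(Y^{aY=0, aD} = 1),  aD ∈ {0, 1},

then faces three compounding error sources, which this package computes
and separates for the two standard weighted estimators:

    E[est] − SDE0^{aD} =  {ostensible − actual target}     (estimand error)
                        + {statistical target − ostensible} (non-identification error)
                        + {E[est] − statistical target}     (statistical error)

* **dgp** — a fully parameterized point-treatment law for `(U, L, A, D, Y)`
  with logistic models for the competing event and the event of interest
  (`dgp_params()`, `generate_point_data()`, `scenario_presets()`).
* **estimands** — exact enumeration of all causal targets, observed-data
  functionals and positivity diagnostics (`true_targets()`,
  `observed_targets()`, `positivity_report()`, `sign_discordant()`).
* **estimators** — the IPCW estimator (competing events censored) and the
  separable-effect ratio-weighted estimator, with weight diagnostics
  (`fit_nuisance()`, `ipcw_cde_hat()`, `ipw_sde_hat()`, `weight_summary()`).
* **decomposition** — the three-way bias decomposition and analytic grid
  scans (`decompose_errors()`, `grid_scan()`, `param_grid_sample()`).
* **simulation** — a deterministic Monte Carlo engine comparing the two
  estimators' variances, in particular under *near positivity violations*
  where censoring weights explode but ratio weights stay bounded
  (`run_simulation()`, `variance_table()`).
* **longitudinal** — discrete-time generalizations: pooled logistic
  competing-event hazards, weighted cumulative-incidence curves, bootstrap
  percentile intervals, and a synthetic two-arm trial generator
  (`fit_discrete_hazard()`, `ipcw_risk_curve()`, `sde_risk_curve()`,
  `bootstrap_contrasts()`, `generate_synthetic_trial()`).

## Worked example

```r
library(separisk)

p <- dgp_params(pL = 0.5, pU = 0.5,
                theta = c(-1, 1, 0.5, -0.5, 1, 0.5, 1),
                beta  = c(-1, 1, 0.5, 0.5, 1, -0.5, 0.5))
causal_targets(p)
#> Causal and statistical targets
#>   CDE0      =  0.1944   SDE0(aD=0) =  0.1081   SDE0(aD=1) =  0.0703
#>   CDEobs    =  0.1969   SDEobs(aD=0) =  0.1110   SDEobs(aD=1) =  0.0717
```

The true controlled effect (0.1944) and separable effects (0.1081, 0.0703)
differ substantially — estimand error — and because both event processes
depend on the unmeasured `U`, each observed-data functional (`CDEobs`,
`SDEobs`) differs from its causal target — non-identification error.
Estimating on a sample shows the third layer:

```r
d <- generate_point_data(p, n = 5000, seed = 11)
f <- fit_nuisance(d)            # saturated: cell proportions of D = 1
ipcw_cde_hat(d, f)
#> IPCW-CDE: estimate = 0.1936 (arm1 0.6536 - arm0 0.4599; n = 2471/2529; max weight 5.32)
ipw_sde_hat(d, f, aD = 0)
#> IPW-SDE[aD=0]: estimate = 0.1123 (arm1 0.3456 - arm0 0.2333; n = 2471/2529; max weight 2.37)

decompose_errors(ipcw_cde_hat(d, f)$estimate, 0, causal_targets(p), "ipcw", aD = 0)
#> Error decomposition: IPCW estimator vs actual target SDE0(aD=0) = 0.1081
#>   estimand error            0.08627
#>   non-identification error  0.00248
#>   statistical error        -0.00325
#>   total bias                0.08550
#>   variance 0,  MSE 0.00731
```

The censoring analysis misses the separable-effect target almost entirely
through estimand error (0.086 of the 0.085 total bias); the statistical
machinery is nearly irrelevant to its failure. The separable-effect
estimator (0.1123 vs. target 0.1081) has no estimand error by
construction.

The six packaged scenarios reproduce the variance comparison under near
positivity violations:

```r
ps <- scenario_presets()
tab <- variance_table(lapply(seq_along(ps), function(i)
  simulation_config(ps[[i]], n = 1e5, reps = 300,
                    base_seed = i * 1e4, aD_values = 0)))
tab[, c("scenario", "var_sde_aD0", "var_cde", "var_ratio")]
```

The separable-effect estimator's variance stays at a few `1e-6` in every
scenario while the IPCW variance inflates past `4e-4` (ratios above 100)
whenever some treatment-covariate stratum has a survivor probability near
zero.

## Command-line wrappers

Thin wrappers over the package functions live in `inst/cli/`:
`estimate.R` (point-treatment estimation from a CSV), `simulate.R`
(scenario variance tables) and `reanalyze.R` (discrete-time trial
reanalysis and synthetic-trial generation). Each prints usage with
`--help`.
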