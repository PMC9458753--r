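# resistfam

Inferring the **timing** (pre-existing vs acquired) and **mechanism**
(random vs drug-induced) of resistance to targeted cancer therapy from
per-mouse tumor-volume time courses — the kind of sparse, noisy caliper data
produced by patient-derived xenograft (PDX) experiments with weekly dosing
(e.g. cetuximab in head and neck squamous cell carcinoma).

The package implements, end to end:

- **A six-member family of resistance ODE models.** Sensitive volume *S* and
  resistant volume *R* under exponentially decaying drug *D* with impulsive
  weekly boluses:

  dS/dt = r_S S − f(S, D) − λ_S D S
  dR/dt = r_R R + f(S, D) − λ_R D R
  dD/dt = −γ D,   γ = ln 2 / 4.75 ≈ 0.1459 /day

  with transition term f = 0 (model 1.x, no acquisition), f = gS (2.x,
  random acquisition) or f = gSD (3.x, drug-induced), each with or without
  pre-existing resistance R(0) > 0 (x.2 vs x.1), plus five untreated growth
  laws (exponential, logistic, Allee, surface, von Bertalanffy) for control
  mice. Viability constraints r_S ≥ r_R and λ_S > λ_R encode the fitness
  cost of resistance.
- **A two-stage per-mouse fitter**: Sobol quasi-Monte Carlo global search
  over biologically reasonable ranges, then stochastic gradient descent
  (uniform log-scaled perturbations, downhill-only acceptance), wrapped in a
  deterministic multistart. Objective: SSE ζ = Σ (y − ŷ)² over non-censored
  points.
- **AIC/BIC model selection** (AIC = n ln(ζ/n) + 2k, BIC = n ln(ζ/n) +
  k ln n) with low/medium/high confidence tiers from the relative gap to the
  runner-up, and cohort-level best/worst tallies.
- **Profile-likelihood identifiability** of the initial resistance fraction
  r⁰ = R(0)/(S(0)+R(0)), re-fitting all remaining parameters on a 0.05 grid.
- **Simulated dose escalation** (16–20 mg/kg, two weeks) summarized by the
  cohort median fold reduction V(0)/V(14) per dose and its average rate of
  change — the signature that separates random from drug-induced resistance.
- **A synthetic-cohort generator** with known ground truth (heterogeneous
  lognormal per-mouse parameters, sparse irregular sampling, multiplicative
  noise, injected outlier spikes) so every stage is testable without any
  external data, plus preprocessing (ellipsoid volume V = l w² π/6, spike
  censoring, trajectory classification, Fisher exact response test).

## Worked example

```r
library(resistfam)

# a synthetic drug-induced-resistance cohort with known ground truth
rec <- cohort_recipe(resistance_spec("3.1"), n_mice = 6, noise_cv = 0.05,
                     outlier_rate = 0, seed = 7)
gen <- generate_cohort(rec)
tc  <- censor_timecourse(gen$cohort$mouse_01)
tc
#> <tumor_timecourse> mouse mouse_01 (treatment): 12 points over days 0-38.2103, 0 censored

# fit three candidate models and rank them (desk-scale budgets)
fits <- lapply(c("1.1", "2.1", "3.1"), function(m)
  multistart_fit(resistance_spec(m), tc, n_starts = 3, n_qmc = 3000,
                 n_iter = 3000, seed = 1))
rank_models(fits)
#> <ic_table> mouse mouse_01
#>   model_id k  n        sse      aic      bic
#> 1      1.1 3 12 10741.7607 87.56385 89.01857
#> 2      2.1 6 12   792.4409 62.28254 65.19198
#> 3      3.1 6 12   709.9315 60.96314 63.87258
#>   best AIC: 3.1 (low confidence), best BIC: 3.1 (low confidence)
```

The no-resistance model (1.1) is decisively worst — the data cannot be
explained without resistance — while the two acquisition mechanisms fit
almost equally well (a "low confidence" call), which is exactly why the
volume data alone cannot identify the mechanism. The dose-escalation replay
of the fitted cohort provides the discriminating signature:

```r
esc <- escalation_study(lapply(names(gen$cohort), function(id)
  multistart_fit(resistance_spec("3.1"), censor_timecourse(gen$cohort[[id]]),
                 n_starts = 3, n_qmc = 3000, n_iter = 3000,
                 seed = match(id, names(gen$cohort)))),
  resistance_spec("3.1"))
esc
#> <escalation_result> model 3.1 over 16-20 mg/kg
#>   dose median_fold
#> 1   16       2.437
#> 2   17       2.586
#> 3   18       2.741
#> 4   19       2.903
#> 5   20       3.073
#>   average rate of change: 0.159 fold per mg/kg
```

A drug-induced cohort escalates shallowly (more drug also creates more
resistance); a random-acquisition cohort fitted the same way shows a several
times steeper slope (≈1.4 fold per mg/kg under the default synthetic world)
— measuring this slope experimentally would distinguish the mechanisms.

There is also a CLI front end (`exec/resistfam`) with subcommands
`synth | preprocess | fit-control | fit | profile | escalate | run`, and
`run_full_analysis()` orchestrates the whole pipeline from one config with
a checksummed manifest.

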