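---
title: "Inferring the timing and mechanism of therapeutic resistance from tumor volume time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the timing and mechanism of therapeutic resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistfam)
```

## The scientific problem

Targeted therapies such as the EGFR antibody cetuximab often fail in head and
neck squamous cell carcinoma because tumors are, or become, resistant. Three
qualitatively different routes matter for therapeutic design: resistance that
*pre-exists* treatment (selection of a resistant subclone), resistance
*acquired at random* during treatment (drug-independent switching), and
resistance *induced by the drug itself* (dose-dependent switching). The only
routinely available longitudinal readout in patient-derived xenograft (PDX)
experiments is caliper-derived tumor volume. `resistfam` asks, operationally:
given per-mouse volume time courses under weekly dosing, which members of a
family of resistance models are consistent with the data, which can be ruled
out, and what additional measurements (initial resistance fraction,
dose-escalation cohorts) would discriminate the rest?

## The model family

Untreated (control) growth is described by one of five single-compartment
laws — exponential ($\dot V = rV$), logistic ($\dot V = rV(1-V/K)$), Allee
($\dot V = rV(1-V/K)(V/m-1)$), surface ($\dot V = aV(V+b)^{-1/3}$) and von
Bertalanffy ($\dot V = aV^{2/3} - bV$) — fitted per mouse and compared by
information criteria. Treated tumors are split into sensitive volume $S$ and
resistant volume $R$ with exponentially decaying drug concentration $D$:

$$
\dot S = r_S S - f(S,D) - \lambda_S D S,\qquad
\dot R = r_R R + f(S,D) - \lambda_R D R,\qquad
\dot D = -\gamma D .
$$

The transition term $f$ selects the mechanism: $f = 0$ (none), $f = gS$
(random acquisition), $f = gSD$ (drug-induced). Allowing or forbidding
$R(0)>0$ gives the six family members 1.1–3.2 with $k = 3, 6, 6, 7, 6, 7$
free parameters. Resistance is assumed to carry a fitness cost
($r_S \ge r_R$) and to blunt drug kill ($\lambda_S > \lambda_R$); parameter
sets violating these are "non-viable" and excluded everywhere. The decay
rate is fixed at $\gamma = \ln 2 / 4.75 \approx 0.1459\,\mathrm{d}^{-1}$
(4.75-day serum half-life), not fitted. Weekly 5 mg/kg administration is
modeled impulsively: $D$ jumps by the dose at each administration and the
integrator restarts at the jump; values reported at a dose time are
post-jump (pre-jump available via `pre_dose = TRUE`).

## Fitting

Each mouse × model problem minimizes the sum of squared errors
$\zeta_i = \sum_t (y_i(t) - \hat y_i(t))^2$ over the non-censored points, in
two stages:

1. **Sobol quasi-Monte Carlo search.** `n_qmc` points of an unscrambled
   Sobol sequence are scaled into biologically reasonable ranges
   (rates in $[0, 0.1]$, $r_S$ in $[0, 0.2]$, initial conditions in
   $[0, 2V_0]$ with the additional joint constraint
   $S_0 + R_0 \in (0, 2V_0]$, $K \in [V_0, 10^5]$, $m \in [0, 10V_0]$);
   non-viable points are discarded and the SSE-minimizing survivor is kept.
2. **Stochastic gradient descent.** Every parameter is perturbed by an
   independent uniform draw from $[-10^{\alpha-1}, 10^{\alpha-1}]$ where
   $\alpha=\lfloor\log_{10}|p|\rfloor$ (at $p = 0$, $\alpha = -3$); moves
   that are non-viable or increase the SSE are rejected — no uphill
   acceptance, so the accepted-SSE trace is non-increasing.

The pair is repeated `n_starts` times (headline defaults: 15 starts,
$1.5\times 10^6$ points, $5\times 10^5$ iterations; the test suite uses
desk-scale budgets and says so), each start consuming a fresh offset block
of the Sobol sequence and a sub-seeded RNG stream, and the overall SSE
minimum is returned with a per-start audit trail. Everything is bit
reproducible from `(seed, budgets)`.

Sampling bounds not fixed by the source setting: the surface and von
Bertalanffy coefficients have no stated ranges, so `a` spans $[0,2]$ (its
effective per-day growth rate is $a/O(V^{1/3}) \approx a/6$ at 200 mm³, so
2 caps the effective rate near 0.3/d, comfortably above any observed
doubling), surface `b` is a volume offset in $[0, 10V_0]$, and the von
Bertalanffy loss `b` is rate-like in $[0, 0.1]$.

## Model selection

From each fit, $AIC = n\ln(\zeta/n) + 2k$ and $BIC = n\ln(\zeta/n)+k\ln n$
with $n$ the non-censored point count. Lowest IC wins; ties break toward
smaller $k$, then lexicographic model id. A confidence tier summarizes the
relative gap $|IC_2-IC_1|/\max(|IC_1|,1)$ between winner and runner-up:
low ($\le$5%), medium (5–10%), high (>10%). The reported analyses used two
inconsistent threshold sets (5/10% in figure captions, 5/15% in prose); the
captions govern the figures this package mirrors, so they are the default
and the prose variant is available via `thresholds = c(0.05, 0.15)`. The
denominator is floored at 1 because SSE-based ICs can legitimately be near
or below zero.

## Preprocessing

Volumes derive from two-axis caliper measurements via $V = lw^2\pi/6$.
Censoring removes biologically implausible spikes: an interior point is
flagged when volume more than doubles versus the previous point within 4
days *and* the next point falls back below the spike
(`sustain_tol = 1`) — untreated doubling is never faster than about two
weeks, so an unsustained 3–4-day doubling is a measurement artifact.
Censored points are excluded from all fitting, SSE and classification but
retained in files for audit, and the rule is idempotent. Trajectories are
classified by the last non-censored volume relative to $V_0$ with a ±20%
stability band (the qualitative classes in the source are not given a
numeric rule; endpoint comparison with one parameter reproduces them).
Cohort response is tested by a two-sided Fisher exact test on
(decreasing vs not) × (control vs treatment).

## Identifiability of the initial resistance fraction

For models with $R(0)>0$, the initial resistance fraction
$r^0_{frac} = R(0)/(S(0)+R(0))$ is profiled over the grid
$0, 0.05, \ldots, 1$: at each fixed fraction the remaining parameters are
re-fitted with the *total* initial volume $T$ kept free
($S_0 = (1-v)T$, $R_0 = vT$, $T \in (0, 2V_0]$), so the constrained problem
nests the unconstrained one. The qualitative "quadratic with a clear
minimum" criterion is quantified as: argmin interior to the grid *and* both
endpoint SSEs at least 10% above the minimum (`rel_rise`, configurable).
Profiles run 21 refits per mouse, so their budgets default well below the
headline fits.

## Dose escalation

Fitted mice are replayed under weekly dosing at 16–20 mg/kg (1 mg/kg steps)
for two weeks (doses at days 0 and 7) and summarized by the per-dose cohort
median of the fold reduction $V(0)/V(14)$ — model-predicted $V(0)=S_0+R_0$,
since the quantity is purely in silico — plus the average rate of change of
that median across the range. Random-acquisition cohorts respond more
steeply to escalation than drug-induced cohorts, because with $f = gSD$ a
higher dose also drives more resistance formation; this contrast is the
discriminating signature the escalation experiment is designed to expose.

## The synthetic world

`cohort_recipe()` / `generate_cohort()` produce cohorts with known ground
truth emulating the experimental setting: 28 mice (cohorts of 25–29 in the
source), $V_0 \sim$ lognormal(mean 200 mm³, cv 0.2) — treatment starts at
~200 mm³ —, weekly 5 mg/kg dosing, measurement gaps uniform in 3–4 days to
day 42 (11–15 points per mouse), multiplicative lognormal noise (default
cv 0.10; caliper error scales with size — the noise model is this package's
choice, the source states none), and isolated 2.5–8× outlier spikes at
rate 0.05 so the censoring rule has true positives to find. Inter-mouse
parameter dispersion is unknown without the original data; the defaults
(lognormal, e.g. $r_S$: mean 0.09/d cv 0.3, $\lambda_S$: 0.025 cv 0.3,
$g$: 0.01 cv 0.5, fraction 0.25 cv 0.3) were fixed once so that (a) the
control growth-rate scale respects the observed 13-day fastest doubling
and (b) a treated cohort reproduces the observed qualitative class mix
(majority increasing, minority decreasing/stable). They were not adjusted
afterwards.

What a green test does and does not establish: the generator produces
smooth single-clone-pair dynamics with exchangeable mice; it does not
emulate euthanasia dropout, batch sacrifice, inter-measurement correlation,
or model misspecification, so recovery results bound what the pipeline can
do on ideal data of the stated sparsity/noise, not what it achieves on real
xenografts.

## Numerical choices

- Adaptive Dormand–Prince RK45, defaults `rtol = 1e-8`, `atol = 1e-10`
  (configurable). The originally contemplated 1e-6 left ~1.2e-6 relative
  error against the impulsive-dosing closed form after many restart
  segments, violating the 1e-6 oracle-equivalence requirement; tightening
  costs ~nothing for 1–3 state systems (~10 µs per simulation).
- Dose impulses are hard integration restarts, never stiff forcing terms.
- Sobol: unscrambled Gray-code construction with Joe–Kuo direction numbers
  (dimensions to 10), verified bit-exact against an independent reference;
  multistart repetitions take consecutive `skip` blocks of one sequence.
- Perturbations producing any negative parameter are rejected, not clipped
  (clipping biases the walk toward the boundary); gradient descent enforces
  viability but not the sampling bounds, which matches the stated
  definition of biological viability.
- A perfect fit ($\zeta = 0$) yields $-\infty$ information criteria with a
  warning rather than an error.
- Ties and degenerate inputs: single-model IC tables get an `NA` tier;
  all-censored time courses refuse classification; `m = 0` makes the Allee
  right-hand side singular and is treated as non-viable.

## Known limitations

- **Per-mouse rate parameters are practically non-identifiable from volume
  data.** $r_S$ and $\lambda_S$ enter the sensitive compartment only through
  $r_S - \lambda_S D(t)$; their separation rests on the within-week sawtooth
  of $D$, which 3–4-day sampling with 5–10% noise barely resolves. A
  Cramér–Rao computation on the default synthetic world gives per-mouse
  relative standard errors for $r_S$ above 100%. The fitter still meets its
  contracts (it matches or beats the truth's SSE), but point estimates of
  individual rates should not be interpreted — this is precisely why the
  profile-likelihood and dose-escalation analyses exist.
- The no-uphill descent is a local refiner; global coverage comes entirely
  from the QMC stage and the multistart, so very small `n_qmc` can miss
  basins.
- Model 2.2 profiles are supported but not part of the default analysis
  (the information-theoretic stage already rules that combination out).
- The escalation study replays *fitted* parameters; its contrast inherits
  any bias in those fits.
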