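---
title: "Estimating false-positive diagnosis ratios from aggregated claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating false-positive diagnosis ratios from aggregated claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpclaims)
```

## The model

For an irreversible chronic condition, the illness-death model has three
states — healthy, diseased, dead — with incidence rate $i(t,a)$ out of the
healthy state and mortality rates $m_0$, $m_1$ for the healthy and the
diseased.  Writing $R = m_1/m_0$ for the mortality rate ratio and $m$ for
the all-cause mortality of the whole population, the age-specific
prevalence $p(t,a)$ satisfies

$$(\partial_t + \partial_a)\,p \;=\; (1-p)\,i \;-\;
  m\,\frac{p\,(R-1)}{1 + p\,(R-1)}.$$

The operator $\partial_t + \partial_a$ is an ordinary derivative along a
*characteristic line* $t - a = \text{const}$: a birth cohort ageing through
calendar time.  Two cross-sectional prevalence surveys taken $\delta$ years
apart therefore pin down the left-hand side by a finite difference, while
incidence, mortality and the rate ratio pin down the right-hand side — any
mismatch must be explained by errors in the data.

Coded diagnoses in claims data behave like an imperfect diagnostic test
with sensitivity $se$ and specificity $sp$.  The standard (Rogan–Gladen
style) corrections

$$p = \frac{p^{(obs)} - 1 + sp}{se + sp - 1}, \qquad
  i = \frac{i^{(obs)} - 1 + sp}{se + sp - 1}$$

map observed to true values.  (The second line applies the proportion
formula to a rate; that is deliberate and matches how the method is used
on claims data, where observed incidence is small.)  Substituting both
corrections into the prevalence equation gives, for a fixed assumed $se$,
one scalar equation in the single unknown $sp$; the package solves it
numerically.  The reported quantity is the false-positive ratio
$FPR = 1 - sp$: the proportion of truly non-diseased people who carry a
coded diagnosis.

Both surveys and the incidence are assumed to share one $(se, sp)$ pair
per age and sex.  The types accept distinct pairs in principle, but the
pipeline fixes them equal: prevalence and incidence in a single claims
source derive from the same coded diagnoses, so separate error parameters
would not be identifiable from these data anyway.

## Discretisation and root finding

For an evaluation age $a$, the characteristic segment runs from
$(t_1, a - \delta/2)$ to $(t_2, a + \delta/2)$ with $\delta = t_2 - t_1$.
The residual solved by `estimate_specificity()` is

$$\frac{p^c_2 - p^c_1}{\delta} \;-\;
  \mathrm{rhs}\!\left(\bar p,\; i^c,\; m,\; R\right),
  \qquad \bar p = \tfrac{1}{2}(p^c_1 + p^c_2),$$

with all corrected quantities evaluated under the candidate $sp$;
incidence, mortality and the rate ratio are read from their fitted
surfaces at the segment midpoint and treated as constant over the window.
Using the mean of the two corrected endpoint prevalences in the right-hand
side gives second-order (midpoint) accuracy; a switch
(`prevalence_rhs = "midpoint_obs"`) instead corrects the fitted prevalence
at the midpoint itself, since it is not decidable from first principles
which variant a closed-form derivation would produce.  The difference
between the two is far below the other error sources.

The root is bracketed on
$$\bigl[\max(1 - \min(p^{(obs)}_1, p^{(obs)}_2),\; 1 - se,\; 1 - i^{(obs)})
  + \varepsilon,\; 1\bigr],$$
which is exactly the set of specificities for which all three corrected
quantities stay in their domains ($\varepsilon = 10^{-9}$ keeps the
endpoint interior).  The true specificity always lies inside: a genuine
disease process has positive corrected incidence and non-negative
corrected prevalence.  Within the bracket the residual is solved to a
tolerance of $10^{-10}$ on $sp$ (Brent's method for single segments, a
vectorised bisection across Monte-Carlo scenarios; tests verify the two
agree).  If the residual has no sign change on the bracket, the endpoint
with the smaller absolute residual is returned and the estimate is flagged
*boundary-clipped* — never silently.  Clipped cells enter count summaries
as $FPR = 0$ and are tallied in the run's audit record; a run with more
than 1% clipped cells warns.

## Surface fitting

The four input tables are aggregated by sex, period and age group.  Each
group is represented by its midpoint age (open-ended top groups by their
lower bound plus 2.5 years), and the tables are smoothed by ordinary least
squares on transformed scales:

| quantity    | model                                   | transform |
|-------------|------------------------------------------|-----------|
| prevalence  | `logit(p_obs) ~ ns(age, df) * time * sex` | logit     |
| incidence   | `log(i_obs) ~ ns(age, df) * sex`          | log       |
| mortality   | `log(m) ~ (age + age^2) * sex`            | log       |
| rate ratio  | `log(R) ~ ns(age, df) * sex`              | log       |

Back-transformation guarantees values in the quantity's natural domain.
Natural-spline knots sit at quantiles of the observed midpoint ages with
boundary knots at the extremes, so the fitted curves continue linearly (on
the transformed scale) beyond the data — the safest available behaviour
when the evaluation grid touches the edge of a coarse table.  The
incidence model carries no time term: incidence tables are pooled over a
short window, so a time effect would make the design singular.  The
mortality fit is restricted to ages 15–95, where the quadratic Gompertz
approximation is adequate.  Default spline degrees of freedom are 4
(prevalence), 3 (incidence; a five-group table cannot support more) and 3
(rate ratio).  These defaults are this package's choices — aggregated
tables cannot select them by cross-validation, and with two survey years
linear-continuous and categorical time coding coincide.  Rows with
prevalence exactly 0 or 1 have no logit and are dropped with a counted
warning.  Unweighted least squares is the default; population-weighted
fitting is available behind `weighted = TRUE`.

## The Monte-Carlo pipeline

The sensitivity of coded diagnoses is unknown, so it is sampled uniformly
from 50–99.9% (the plausible range for chronic-disease coding).  By
default each (scenario, age) cell draws independently
(`se_mode = "per_age"`), allowing the assumed sensitivity to vary over
age within a scenario; `se_mode = "shared"` draws once per scenario.  The
default evaluation grid is $a = 25, 32.5, \dots, 85$ with $\delta = 6$
years between surveys; the constructor warns if the grid spacing is not
coarser than $\delta$, since neighbouring estimates would then share data.

For the count step, the scenario's age-specific $FPR$ and the corrected
prevalence (observed prevalence at the later survey year, corrected with
that scenario's own $(se, sp)$ per age — so the number of non-diseased
people is coherent with the scenario's error model) are interpolated
linearly to integer ages 20–100, with constant continuation outside the
grid range (linear extrapolation of a small ratio could go negative).
Population counts given in age groups are spread uniformly across their
member integer ages.  Per scenario,

$$N^{fp} = \sum_{a=20}^{100} (1 - p(a))\,N(a)\,FPR(a)$$

per sex, with the total the exact sum of the sexes.  Distributions over
scenarios are summarised by empirical 2.5/50/97.5% quantiles using linear
interpolation between order statistics (R's default type 7), fixed here
for reproducibility.  All randomness flows from the single configuration
seed; re-running with the same configuration is bit-identical.

## The synthetic-data generator

`idm_scenario()` defines a time-homogeneous ground truth: per sex, a
log-linear (optionally log-quadratic, so it can peak in old age) incidence,
Gompertz mortality, a log-linear rate ratio floored at 1, a
piecewise-linear $FPR(a)$ profile, and a true sensitivity.  True
prevalence is obtained by integrating the prevalence equation along
characteristics with a classical fixed-step fourth-order Runge–Kutta
scheme (default step 0.1 years; deterministic and verifiable by step
halving and by the closed form $p = 1 - e^{-\int i}$ when $R \equiv 1$).
Observed tables evaluate the truth at stratum midpoints, push prevalence
and incidence through the forward misclassification map, and emit the
claims-style stratification: prevalence in 17 age groups (&lt;15, 15–19,
…, 90+) at two survey years, incidence pooled over a three-year window in
five broad groups, mortality and rate-ratio tables noise-free.  Optional
binomial noise replaces observed prevalence by a binomial draw with the
stratum population size; incidence stays noise-free by default because
claims incidence rests on millions of person-years, so prevalence noise
dominates.  Every dataset carries its answer key; the analysis pipeline
never reads it.

`default_scenario()` fixes one canned truth with claims-like magnitudes:
prevalence rising to tens of percent in old age, incidence peaking near
1.3 per 100 person-years around age 72, $R$ falling from about 4 in
midlife towards 1.5, a male FPR profile rising slowly from 1 to 5 per
1,000 and a female profile peaking at 12 per 1,000 near age 60, true
sensitivity 0.97, and a two-sex population of about 71 million.  Group
evaluation uses midpoints rather than person-time averages, matching how
the fitting side assigns ages.  Time-homogeneity is deliberate: it admits
exact oracles (the two surveys coincide, and the directional derivative
reduces to $dp/da$), while a linear-in-time incidence drift option exists
to exercise the time terms of the prevalence fit.

## What the tests do and do not establish

The test suite verifies, among others: exact arithmetic of the model
right-hand side and the correction round trip (to $10^{-12}$); fourth-order
convergence of the forward solver; that the specificity inversion recovers
the generating value to better than $10^{-3}$ across a factorial grid of
specificities (0.95–0.999), sensitivities (0.7–0.98) and prevalence levels
(0.01–0.3) when the sensitivity is correctly specified; and that a
constant FPR profile is recovered within $\pm 10^{-3}$ at every grid cell
when the fitted surfaces represent the truth almost exactly (fine strata,
generous spline df).

Two properties fail by honest measurement, and understanding why is part
of the method's scientific account:

* **Robustness to the assumed sensitivity is prevalence-limited.**  The
  corrections scale with $1/(se + sp - 1)$, so a mis-specified $se$
  perturbs the corrected quantities proportionally to their size.  At
  prevalence up to about 0.1 the estimated $sp$ moves by less than
  $10^{-3}$ as the assumed $se$ sweeps the whole 0.5–0.999 range — the
  robustness that justifies the probabilistic treatment.  At prevalence
  near 0.3 the sweep moves the estimate by several times that tolerance
  (the effect is intrinsic, not a discretisation artefact: it persists as
  $\delta \to 0$).  This is exactly why the age-specific FPR draws fan out
  at old ages and why results are reported as distributions rather than
  points.

* **Surface smoothing distorts small FPRs.**  The inversion differentiates
  the fitted prevalence surface over a 6-year window, so a smoothing error
  $\epsilon(a)$ in observed-prevalence units enters the estimate roughly as
  $(\epsilon(a + \delta/2) - \epsilon(a - \delta/2))/\delta$.  With
  claims-like stratification (17 groups, spline df 4) the fit errs by only
  a few percent of $p^{(obs)}$, yet that already translates into absolute
  FPR distortions comparable to FPR values of a few per 1,000 — raising
  the spline df does not remove it, because the true logit-prevalence
  curve of an illness-death process is not a spline.  End-to-end recovery
  of an age-varying profile on the canned fixture is therefore accurate in
  shape and peak location but not uniformly within 10% per age, and the
  pipeline's 95% interval of the total count can exclude the generating
  truth when the true sensitivity lies at the edge of the sampled range
  (the Monte-Carlo median then inherits the sensitivity-misspecification
  bias described above).  Real-data applications should read the
  age-specific FPR as an order-of-magnitude profile with honest
  Monte-Carlo spread, not as a pointwise-unbiased estimate.

Passing tests on the generator also do not establish anything about
secular trends, reimbursement-driven coding drift, inconsistent case
definitions between prevalence and incidence, or misclassification in the
rate-ratio source — the generator does not emulate those features, and the
method assumes them away.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| root-finder tolerance | $10^{-10}$ on $sp$ | far below all statistical error |
| bracket interior offset $\varepsilon$ | $10^{-9}$ | keeps corrections defined without excluding near-boundary roots |
| forward-solver step | 0.1 years | RK4 error $\ll 10^{-8}$ at this smoothness |
| domain tolerance on corrections | $10^{-9}$ | absorbs round-off at the $[0,1]$ edges; larger violations raise inconsistency errors |
| open-group representative age | lower bound + 2.5 years | half a standard 5-year group |
| quantile definition | type 7 | fixed for reproducibility |
| grid / $\delta$ | 25–85 by 7.5 / 6 years | spacing must exceed the survey gap |
| sensitivity range | 0.5–0.999 uniform | plausible range for chronic-disease coding |

Problem sizes used in the shipped checks — 10,000 scenarios for routine
runs and 100,000 for the stability comparison — were chosen because the
count medians agree to well under 1% between them, so nothing scientific
hinges on the larger number.

## Known limitations

The model covers irreversible conditions only (no remission), treats
rates as time-constant within the survey window, and assumes the
mortality-rate-ratio source is itself free of misclassification.  Counts
outside the evaluation grid (ages 20–25 and 85–100) rest on constant
extrapolation of the nearest estimated FPR.  Where observed prevalence is
incompatible with a candidate $(se, sp)$ — corrected values outside their
domains — the package raises typed inconsistency errors rather than
clamping, and boundary-clipped inversions are flagged and audited.
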