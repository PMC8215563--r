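---
title: "Modelling within-meal food-removal curves: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within-meal food-removal curves: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealcurve)
```

## The problem

A plate scale wired to a recorder (a "universal eating monitor" such as the
Mandometer) produces, for each meal, a time series of plate weight — the
food-removal curve. Two phenotypes of interest fall straight out of such
curves: how much food a person serves themselves (starting weight, grams) and
how fast they eat (the downward slope of the curve, grams/second). Because
repeated weight snapshots sit inside meals, and several meals sit inside each
participant, observations are doubly clustered, and any honest analysis has
to partition variance into within-meal, between-meal and between-participant
components.

`mealcurve` implements that analysis end to end: a synthetic-cohort generator
with the full hierarchical structure (so that every estimator in the package
can be exercised against known truth), the artifact-smoothing rule, the
three-level mixed model with BLUP eating speeds, and the clustered
power/sample-size arithmetic for studies that record several meals per
person.

## The model

For participant $i$, meal $j$, snapshot $k$, with a three-level exposure
(genotype, BMI class, or dietary-fat class; indicator variables for the two
non-reference levels):

$$
w_{ijk} = \beta_0 + u_{0i} + v_{0ij}
        + (\beta_1 + u_{1i} + v_{1ij})\,t_{ijk}
        + \beta_2 1_{g_2} + \beta_3 1_{g_3}
        + \beta_4\, t_{ijk} 1_{g_2} + \beta_5\, t_{ijk} 1_{g_3}
        + \varepsilon_{ijk}
$$

with $(u_{0i}, u_{1i})$ bivariate normal at the participant level,
$(v_{0ij}, v_{1ij})$ bivariate normal at the meal-within-participant level,
and $\varepsilon_{ijk} \sim N(0, \sigma^2_\varepsilon)$ homoscedastic and
independent. $-\beta_1$ is the reference group's average eating rate;
$\beta_2, \beta_3$ shift average meal weight and $\beta_4, \beta_5$ shift
eating rate for the other two groups. A *sensitivity* variant drops both
random slopes and keeps only the two random intercepts; in that variant the
slope variance terms are omitted entirely rather than pinned at zero.

Estimation is by REML (`fit_meal_model()`, backed by `lme4::lmer`), with ML
available as an option. Inference on fixed effects is Wald/normal (estimate
$\pm 1.96\,$SE and two-sided normal p-values); no small-sample df correction
is attempted. Intercept–slope covariances at each level are estimated by
default and can be constrained to zero with `estimate_cov = FALSE`.

Each meal's eating speed (`extract_meal_speeds()`) is the negative of its
model-implied slope: the fixed slope of the participant's group plus the
participant's and the meal's BLUPs of the random slope, reported as a
positive consumption rate. BLUPs are shrinkage estimates, so the spread of
BLUP speeds is slightly smaller than the spread of per-meal least-squares
slopes; with dozens of snapshots per meal the shrinkage is mild.

## Smoothing rule

Raw recordings show transient upward spikes when users rest cutlery or a
hand on the plate. Since food only leaves the plate, weight is only allowed
to decrease: a snapshot that exceeds the previous *smoothed* value is
replaced by it. The output is the running minimum of the series —
non-increasing, pointwise no larger than the input, idempotent, and leaving
the first snapshot (the served portion) untouched. We compare against the
previous smoothed value rather than the previous raw value because only the
former guarantees a globally non-increasing curve; comparing against raw
values would leave residual increases after multi-snapshot spikes.

Exact spike removal has a precise meaning here: if nothing is eaten while
the spike lasts (the underlying curve is flat across the affected
snapshots), the smoothed spiked curve is identical to the spike-free curve.
If food is removed *during* a spike, that information is destroyed by the
artifact itself; the rule then holds the weight constant over the event,
which is the best available imputation. The test suite checks the exact-
recovery property on step-shaped (bite-like) curves with spikes injected
into flat stretches, and the running-minimum equivalence on arbitrary
curves against an independent loop oracle.

Leading zero-weight snapshots (scale switched on before the plate is loaded)
are trimmed by `trim_leading_zeros()`, and time is re-zeroed so time 0 means
"full portion on the plate".

## What the generator emulates

`simulate_cohort()` runs the model above forward. Defaults describe a cohort
of young adults eating self-selected evening meals, and were fixed once from
the descriptive scale of such cohorts:

* mean starting portion 355.74 g and mean meal duration about 545 s, giving
  a baseline eating rate $\beta_1 = -0.653$ g/s;
* variance overwhelmingly at the meal level: participant intercept variance
  500 g², meal intercept variance 14600 g², residual variance 25 g², so the
  marginal start-weight SD is $\sqrt{500+14600+25} = 123$ g; participant
  slope variance 0.002 (g/s)², meal slope variance 0.088 (g/s)², so the
  marginal slope SD is $\sqrt{0.002+0.088} = 0.3$ g/s. At a reference time
  of 545 s these components give a between-meal ICC of about 0.97 — the
  regime in which repeated meals from one person are almost as informative
  as meals from new people;
* genotype exposure under Hardy–Weinberg equilibrium at A-allele frequency
  0.44 (`assign_genotypes()`), with three-class BMI and fat-tertile
  exposure models available; group offsets default to zero;
* intercept–slope covariances default to zero at both levels;
* one snapshot every 5 s (device frequency is hardware-dependent; the value
  only sets the within-meal grid density and is configurable), meals capped
  at 1800 s;
* cutlery-spike artifacts as a homogeneous Poisson process, 0.01 events/s,
  +40 g for 2 snapshots — artifact plumbing chosen to look like raw device
  traces, not a calibrated model of user behaviour;
* each meal is truncated at the first snapshot where the noise-free expected
  weight reaches zero (the plate is empty), and observed weights are floored
  at 0 g.

An optional quadratic `deceleration` term (g/s², non-positive) produces
"decelerator" eaters whose rate declines within the meal; it defaults to 0
and is not part of the fitted model.

What the generator deliberately does **not** emulate: bite-and-pause
microstructure (real curves are steps, not noisy lines), autocorrelated
within-meal noise, device quantization, missing snapshots, or any link
between exposure group and eating behaviour unless group offsets are set.
Passing tests therefore demonstrate correctness of the estimators under the
model's own assumptions — not robustness to the ways real curves violate
them.

One structural subtlety is intentional: because meals end when the plate is
empty, meal length depends on the realized random effects (steep eaters are
observed for less time). This mildly violates the fitted model's assumption
that the observation grid is exogenous, and is visible as a small downward
bias in the estimated ICC on default cohorts. The parameter-recovery test
suite instead uses a short fixed observation window (180 s, 15 s grid,
moderate variances) in which no meal empties the plate, so the design is
exogenous and bias/coverage checks isolate the fitter itself.

## Intra-class correlation and power

With random slopes, the variance attributable to each level depends on time,
so a single between-meal ICC requires a reference time $t$:

$$
\mathrm{ICC}(t) = \frac{\sigma^2_{v0} + t^2\sigma^2_{v1} + 2t\sigma_{v01}}
  {\sigma^2_{u0} + t^2\sigma^2_{u1} + 2t\sigma_{u01}
   + \sigma^2_{v0} + t^2\sigma^2_{v1} + 2t\sigma_{v01}
   + \sigma^2_\varepsilon}.
$$

`compute_icc()` defaults $t$ to the mean meal duration of the fitted data.
This time-referenced construction is one defensible way to collapse
intercept and slope variance (which have different units) into one number;
any alternative (e.g. ignoring slope variance entirely) changes the ICC and
hence the design effects, so the choice is exposed through `at_time`.

Sample-size arithmetic (`power_analysis()`):

* `n_per_group()` returns the smallest per-group $n$ for a two-sided
  two-sample comparison; the default closed form is the normal
  approximation $n = 2(z_{1-\alpha/2}+z_{\mathrm{power}})^2 (\sigma/\delta)^2$,
  rounded up — for a 0.5-SD effect at $\alpha = 0.05$ and 80% power this
  gives 63 per group regardless of the SD's value. A noncentral-$t$ variant
  (`method = "t"`, via `stats::power.t.test`) is slightly more conservative.
  Because published per-group numbers for this design problem do not always
  follow from the standard closed form, the clustered plan takes the base
  number of meals as an explicit input rather than deriving it irrevocably.
* `design_effect()` is $1 + (k-1)\,\mathrm{ICC}$ for $k$ meals per person;
  `clustered_plan()` multiplies the base meals by it, ceiling first the
  meals and then the individuals (`individuals = ceil(total/k)`). With an
  ICC of 0.97 and 219 base meals this yields 432 meals / 216 people at
  $k = 2$ and 215 people at both $k = 3$ and $k = 4$ — at such a high ICC,
  extra meals per person buy almost nothing.
* The self-consistency of the normal approximation is verified by simulating
  two-sample $t$-tests at the returned $n$ (10⁴ replicates) and requiring
  empirical power of at least the target minus two Monte-Carlo SEs.

## Exposure coding

BMI bands are half-open: normal $[19, 25)$, overweight $[25, 30)$, obese
$[30, \infty)$ kg/m². Values below 19 are outside every band and are flagged
`underweight` with a warning, never silently folded into "normal". Fat
bands: low $<30$%, medium $[30, 35)$%, high $\ge 35$% of meal energy — the
boundary value 35% is assigned to "high" so the three bands are exhaustive.
`compute_maf()` reports the frequency of the A allele,
$(2 n_{AA} + n_{AT}) / (2n)$, and is deliberately *not* folded to
$\le 0.5$: the A allele is called minor by convention in this literature.

## Numerical choices

* **Time rescaling.** Fitting in raw seconds puts intercepts (~10² g) and
  slopes (~10⁻¹ g/s) four orders of magnitude apart in the random-effects
  covariance, which stalls the optimizer. The model is fitted on time scaled
  to $[0,1]$ and every slope-scale quantity (fixed effects, SEs, variance
  components, BLUPs) is converted back to per-second units. Rescaling $m$
  slope design columns shifts the restricted log-likelihood by exactly
  $m\log(t_{\max})$ through the $\log|X'V^{-1}X|$ term, and the reported
  `reml_loglik` is corrected back to the seconds parameterization — the test
  suite verifies it against a directly assembled marginal-covariance
  restricted likelihood to $10^{-6}$ relative tolerance.
* **Degenerate fits.** Variance components at the boundary (zero) are
  reported as zero with lme4's singular-fit message passed through;
  optimizer non-convergence raises an error carrying the optimizer code and
  messages rather than returning a half-converged object.
* **PSD validation.** Each configured 2×2 random-effect covariance is
  checked for positive semi-definiteness through its eigendecomposition, and
  draws use the symmetric square root, so zero-variance (degenerate) levels
  are legal.
* **Determinism.** All randomness flows from one seed; the same
  configuration and seed reproduce every output byte for byte.
* **Rounding in the clustered plan.** Ceilings are applied meals-first, then
  individuals; this is the convention that keeps both quantities integral
  and conservative.

## Problem sizes used by the checks

The verification suite was sized to single-CPU desk scale, chosen as the
package's own trade-off between Monte-Carlo resolution and runtime: the
parameter-recovery study uses 200 replicates of 100 participants × 3 meals
on the short fixed window (bias within 2 Monte-Carlo SEs; Wald coverage
required in [0.92, 0.98]); the round-trip check uses one 200-participant
cohort under default conditions (start-weight SD, BLUP speed SD and ICC each
recovered within 10%); smoothing is checked against the loop oracle on 10³
random curves; variance-decomposition checks use 500 participants.

## Known limitations

* Wald/normal inference undercovers slightly in very small cohorts; no
  Kenward–Roger or Satterthwaite corrections are provided.
* The ICC is reported at a reference time; there is no single "the" ICC
  under random slopes.
* The generator's linear-with-noise curves make the running-minimum smoother
  mildly biased downward between bites on real step-like data the smoother
  is exact; on noisy lines it clips noise troughs. Start weights (the first
  snapshot) are unaffected.
* Endogenous meal length (plates empty sooner for fast eaters) is a real
  feature of the instrument that the fitted model ignores; its visible
  effect at default settings is a small downward bias in the estimated ICC.
* No bite segmentation, satiety modelling, nutrient coding, or genotype
  QC/imputation: exposure tables are taken as given.
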