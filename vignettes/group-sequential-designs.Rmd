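---
title: "Group sequential designs for small preclinical experiments: models, rules and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group sequential designs for small preclinical experiments: models, rules and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preclinseq)
```

## The problem

Preclinical two-group animal experiments are typically run as block
designs: all animals are used, then a single two-sample test is performed.
Group sequential designs instead preplan interim analyses at fixed
cumulative sample sizes and allow the experiment to stop early — for
efficacy when the evidence is already convincing, or for futility when a
meaningful effect has become implausible. Early stopping saves animals,
but interim testing inflates the type I error unless the per-stage
decision thresholds are adjusted.

`preclinseq` provides the full toolchain for studying this trade-off at
the very small sample sizes typical of laboratory research: boundary
computation, four stopping-rule families, a Monte Carlo trial engine,
simulation-based threshold calibration, and predictive-value analysis
under prior distributions of true effect sizes.

## Outcome model and the synthetic-data generator

All simulations use the canonical standardized-effect model: control
outcomes are $N(0, \sigma^2)$ and treated outcomes $N(d\sigma, \sigma^2)$
with common $\sigma = 1$ by default, so $d$ is Cohen's standardized mean
difference. Data accrue in equal per-stage batches defined by a
`stage_schedule()`; stage $k+1$ always extends the stage $k$ data. Two
worked study sizes are built in:

* **small study**: 18 per group, analysed at 6/12/18 (three stages,
  efficacy stopping only);
* **larger study**: 36 per group, analysed at 18/36 (two stages, efficacy
  and binding futility stopping).

Each simulated trial gets its own seed derived from the master seed
(`derive_seeds()`), so any single trial in a large run can be regenerated
in isolation with `run_trial()`.

What the generator deliberately does *not* emulate: non-normal outcomes,
unequal group variances, attrition, and batch or learning effects across
stages. Passing tests therefore demonstrate the operating characteristics
of the decision procedures under the idealized model, not robustness to
those real-data complications.

For the predictive-value analysis, the true effect size behind each
experiment is drawn from a discrete scenario
(`effect_size_scenario()`). The `"optimistic"` (0.3/0.3/0.4 on
$d = 0, 0.5, 1$) and `"pessimistic"` (0.8/0.15/0.05) presets are
illustrative conventions for effect-rich and mostly-null research fields;
they are not estimates of any particular literature, and both support and
weights can be overridden.

## Boundaries: the crossing-probability recursion

At information fractions $t_1 < \dots < t_K = 1$ the sequential z
statistics are jointly normal with $\mathrm{cor}(Z_i, Z_j) =
\sqrt{t_i/t_j}$ and $E[Z_k] = \delta\sqrt{t_k}$, where the drift for a
two-group comparison is $\delta = d\sqrt{n_K/2}$.
`crossing_probability()` computes per-stage first-crossing probabilities
of a two-sided boundary by the classic stagewise recursion over the
sub-density of the score process $S_k = Z_k\sqrt{t_k}$, whose increments
are independent $N(\delta\,\Delta t_k, \Delta t_k)$. Numerics:

* Gauss–Legendre quadrature with 256 nodes per stage (configurable),
  placed on the exact continuation region $[-b_k, b_k]$ rather than a
  fixed wide interval — no nodes are wasted outside the region, and the
  published two-stage and three-stage constants are reproduced to four
  decimals already at 128 nodes;
* boundary constants are found by bisection on $c \in [1, 6]$ to a
  $10^{-6}$ tolerance on the total crossing probability;
* unequal information fractions are supported throughout, although the
  worked designs use equal ones.

`obf_levels()` (boundary $z_k = c\sqrt{K/k}$), `pocock_levels()`
(constant $z_k = c$) and `haybittle_peto_levels()` (0.001 interim, full
alpha final, no recalibration) cover the classic families;
`custom_levels()` wraps arbitrary level sets and reports their attained
overall alpha.

```{r}
glance(obf_levels(3, 0.05))
tidy(pocock_levels(3, 0.05))
```

One numerical honesty note: the exactly calibrated three-stage
O'Brien–Fleming nominal levels are (0.0005, 0.0141, 0.0451). The level
set (0.0006, 0.0151, 0.0471) widely quoted from O'Brien and Fleming's
original 1979 table corresponds to a slightly lower constant
($c = 1.985$ rather than $2.004$) and attains an overall type I error of
0.0524 rather than 0.0500 — the original published constants were
computed with a less accurate numerical method. The worked small-study
design preset uses the published level set, because that is the design
convention this package's reference operating characteristics are built
on; `custom_levels(c(0.0006, 0.0151, 0.0471))` makes the inflation
visible.

## The four stopping rules

Each stage analysis is the cumulative pooled-variance two-sample t test
(`two_sample_t()`), which also yields the effect estimate
$\hat d = (\bar x_b - \bar x_a)/s_p$ (no small-sample correction, so
$E[\hat d] = d\,\sqrt{\nu/2}\,\Gamma(\tfrac{\nu-1}{2})/\Gamma(\tfrac\nu2)
\approx 1.02\,d$ at $\nu = 34$). Tests are two-sided throughout, and
pooled (not Welch) because the generator shares the variance between
groups. Futility boundaries are binding — a futility stop is always
honored — which is what makes a final-stage nominal level above 0.05
admissible in the larger design.

* **`rule_freq_seq()`** stops for efficacy when the stage p value falls
  below the stage's nominal level, and for futility (interim only) when
  it exceeds `futility_alpha`.
* **`rule_bayes_factor()`** thresholds the default two-sample
  Jeffreys–Zellner–Siow Bayes factor: a Cauchy prior with scale
  $r = \sqrt 2/2$ on $d$ (configurable), $BF_{10}$ computed by adaptive
  quadrature of the noncentral-t likelihood over the prior
  (`jzs_bayes_factor()`). The scale choice is corroborated by the worked
  designs: with $r = \sqrt2/2$ the per-stage stopping rates of the
  thresholded Bayes factor reproduce the reference design's published
  stagewise behaviour almost exactly. Since $BF_{10}$ is strictly
  increasing in $|t|$ at fixed $n$, the mass-simulation engine applies
  the equivalent critical $|t|$ (found once per stage by root search)
  instead of integrating per trial.
* **`rule_credible_interval()`** uses the central posterior interval of
  the mean difference under the standard noninformative (Jeffreys) prior,
  rescaled to the $d$ scale. That posterior is a shifted, scaled Student
  t, so the level-$L$ interval excludes zero exactly when the two-sided
  p value is below $1 - L$ — the mechanism by which calibrated interval
  levels like 99.8%/96.8% correspond to stagewise alphas 0.002/0.032.
  This equivalence is asserted exactly in the test suite.
* **`rule_fixed()`** is the block-design reference: one final test.

## Monte Carlo operating characteristics

`simulate_trials()` runs the staged experiment for each derived seed and
`operating_characteristics()` aggregates: cumulative % significant per
stage, interim futility %, overall rate (power or type I error), mean
animal consumption, and the median $\hat d$ among significant trials —
the winner's-curse summary, recorded at the stopping analysis because
that is the estimate an early-stopped experiment actually reports.
`analytic_fixed_power()` gives the exact noncentral-t power of the block
design (noncentrality $d\sqrt{n/2}$, $2n-2$ df) as an independent
cross-check of the engine; `run_oc_table()` executes the full 24-cell
grid (2 study sizes × 4 approaches × $d \in \{0, 0.5, 1\}$) and writes a
CSV plus a JSON manifest with the master seed and complete rule
definitions.

```{r}
oc <- estimate_operating_characteristics(design_small("freq_seq"),
                                         true_d = 1, n_reps = 2000, seed = 1)
glance(oc)
tidy(oc)
```

## Calibration

`calibrate_design()` tunes one free threshold parameter to a target type
I error (default 0.05, tolerance 0.0025) by bisection. A single stream of
null trials is simulated once and reused for every candidate threshold
(common random numbers), so the achieved rate is a monotone step function
of the parameter and the search cannot oscillate on noise. The free
parameter per rule kind: the alpha itself (fixed), a common multiplier on
the stage alphas (frequentist sequential, preserving the boundary shape),
the efficacy threshold (Bayes factor), or a shared level for the
later stages (credible interval, the first stage staying at its stringent
level). Only one parameter is calibrated at a time; multi-parameter rules
keep their ratio structure fixed. The default calibration stream is
$10^5$ null trials (Monte Carlo SE $\approx 0.0007$, comfortably below
the tolerance).

## Predictive value

`ppv_analysis()` draws a true $d$ per experiment from a scenario, runs
the trial, and estimates $P(\text{significant})$, the positive predictive
values $P(d > 0 \mid \text{significant})$ and
$P(d \ge 0.5 \mid \text{significant})$ (classified by the *true* drawn
effect, not the estimate), and their products — the overall probability
of a significant result that reflects a real effect. A semi-analytic
composition $\sum_d w_d\,\widehat{\text{power}}(d)$ over the per-$d$
power estimates is returned alongside as an internal consistency check,
and the test suite verifies the direct estimates against the closed-form
two-point mixture $w\,\text{power}/(w\,\text{power} + (1-w)\,\alpha)$
built from the analytic fixed-design power.

```{r}
pp <- ppv_analysis(design_larger("freq_seq"),
                   effect_size_scenario("pessimistic"),
                   n_reps = 2000, seed = 2)
glance(pp)[, c("p_significant", "ppv_any", "p_detect_any")]
```

## Numerical and design choices

* **Boundary levels vs analysis scale.** Boundaries are computed on the z
  scale (normal theory) and applied as nominal levels to exact t p
  values. At the very small degrees of freedom of the small study this
  combination attains a slightly higher type I error than the
  normal-theory crossing probability suggests: the three-stage design
  with the published levels has a true rate of about 5.3% (measured at
  $2\times10^5$ replicates and confirmed by an independent
  implementation), against 5.24% normal-theory and 5.0% for an exactly
  recalibrated boundary. The test suite asserts the empirical rate, not
  the normal-theory one.
* **Problem sizes.** Operating-characteristic checks run at $10^4$
  replicates per cell for distributional tests and $10^5$ for the
  headline acceptance quantities, so their Monte Carlo error
  (≈0.07 percentage points on a 5% rate) is small against the tolerances
  being asserted; calibrations use $10^5$ null trials.
* **Tie-breaks and edge cases.** Efficacy uses strict `p < alpha`
  (`BF >= threshold`, zero strictly outside the interval); futility uses
  strict `p > futility_alpha` (interim stages only); the final stage
  never continues. Zero pooled variance raises a dedicated
  degenerate-data error rather than propagating NaN. Rounding of reported
  percentages follows the usual half-up convention of the reference
  tables.
* **Bayes factor quadrature** integrates over the infinite prior range
  with `stats::integrate` at relative tolerance $10^{-10}$ (relaxed
  stepwise to $10^{-6}$ if the adaptive rule reports roundoff near
  $t = 0$); the unit tests pin it to a dense Riemann-sum oracle at
  $10^{-6}$ relative error. The calibration search interpolates
  $\log BF_{10}$ on a 400-point $|t|$ grid with a monotone spline, which
  is exact to well below any threshold-decision resolution.
* **Seeding.** All randomness flows from one master seed through
  `derive_seeds()`; trials are mutually independent and individually
  reproducible, and scenario draws, per-cell grid seeds and calibration
  streams all use derived seeds below $2^{31}$.

## Known limitations

* The normal equal-variance outcome model is an idealization; batch
  effects between stages — a real concern when stages are run weeks
  apart — are out of scope and would require a mixed-model stage
  analysis.
* The scenario presets for the predictive-value analysis are
  placeholders; conclusions about a specific field require field-specific
  weights.
* Alpha-spending functions (flexible re-planning of look times) are not
  implemented; the boundary families here assume the preplanned schedule
  is kept.
* The Haybittle–Peto family is deliberately left uncalibrated, matching
  its common usage; its slight alpha inflation is reported via
  `attained_alpha`.
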