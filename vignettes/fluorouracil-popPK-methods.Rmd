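---
title: "Methods: population PK of fluorouracil and SMI-toxicity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of fluorouracil and SMI-toxicity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fupk)
```

This vignette documents the models, the estimation machinery, the
synthetic-cohort generator and the numerical choices behind `fupk`, in the
spirit of the methods sections of established pharmacometric packages.

## Structural and statistical model

Steady-state therapeutic drug monitoring of a continuous 5FU infusion gives
one algebraic relation per sample: with infusion rate $R_0$ (mg/h) and
clearance $CL_i$ (L/h), the steady-state concentration is
$C_{ss,i} = R_0 / CL_i$ (converted to ng/ml internally). Before steady
state a one-compartment model with linear elimination gives
$C(t) = (R_0/CL_i)\,(1 - e^{-(CL_i/V)t})$. With steady-state-only sampling
the likelihood contains no information about the volume of distribution $V$
or its interindividual variability, so both are fixed (46.1 L, 51.1 %CV)
and the corresponding random effect is marginalized out analytically — its
empirical Bayes estimates are identically zero and its shrinkage is 100%.
This is asserted by tests (the objective function is bitwise invariant to
$V$ and $\omega_V$ on steady-state data).

Interindividual variability of clearance is lognormal,
$CL_i = \widehat{CL}_i \, e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$.
Variability magnitudes are *stored* as standard deviations on the log scale
and *reported* as percent coefficients of variation via
$\%CV = 100\sqrt{e^{\omega^2}-1}$ (`omega_to_cv()`/`cv_to_omega()`).

Covariate effects multiply the typical clearance and are centered at the
study medians (BSA 1.97 m², back-muscle SMI 3.78 cm²/m²), so that
$CL_{pop}$ retains its interpretation as the clearance of the median
patient. Four parametrizations are available per effect:
linear-proportional $1+\theta(x-c)$, exponential $e^{\theta(x-c)}$, power
$(x/c)^\theta$, and piecewise-linear with two slopes hinged at $c$. The
reference model uses the linear-proportional form for BSA and the
exponential form for the SMI effect; at the SMI scale of this population
the two are numerically near-indistinguishable for the estimated
coefficient (0.0570 per cm²/m²), and either can be selected per effect.

Residual error combines an additive and a proportional component,
$\mathrm{Var}(\varepsilon_{ij}) = \sigma_{add}^2 + (\sigma_{prop}
f_{ij})^2$, evaluated at the *individual* prediction ("interaction"). A
legacy subject-level lognormal multiplier on the total residual SD (IIV of
residual variability) is implemented but off by default; it reflects an
initial-model feature that is removed in the revised model because its
estimate is poorly identified with sparse steady-state sampling.

## Marginal likelihood and estimation

The objective function value (OFV) is $-2\log$ of the marginal likelihood
with the additive constant $n\log 2\pi$ omitted, the convention under which
a drop of 3.84 points between nested models corresponds to $p=0.05$ at one
degree of freedom; all nested-model comparisons are invariant to this
constant.

Each subject's marginal likelihood is a one-dimensional integral over
$\eta_i$. The package computes it by **adaptive Gauss–Hermite quadrature
centered and scaled at the conditional mode**: a vectorized, safeguarded
Newton iteration (numeric derivatives, step halving, $|\eta|$ capped at
$8\omega+1$) locates every subject's mode simultaneously; the curvature at
the mode provides both the Laplace log-determinant term and the quadrature
scale. With one node this is exactly the Laplace (FOCE-with-interaction
style) approximation; the default of 21 nodes makes the integral exact to
well below $10^{-6}$, which a test verifies against an independently coded
64-node quadrature oracle. We default to the quadrature-refined objective
because the pure Laplace expansion differs from the exact integral by
$O(10^{-2})$ per handful of subjects at study-like noise levels
($\sigma_{prop}\approx 0.2$) — harmless for selection decisions but larger
than the accuracy we promise for the objective itself. With the legacy
two-dimensional random-effect model the inner problem is solved in 2-D and
the objective falls back to the Laplace expansion.

The outer maximum-likelihood problem is solved by `nlminb` on transformed
parameters (log scale for positive parameters, identity for covariate
coefficients), relative tolerance $10^{-6}$, at most 500 iterations.
Non-convergence is recorded in the result rather than raised. A positive
parameter driven below $10^{-4}$ of its starting value is flagged as a
boundary estimate — the behaviour expected of the additive error term when
a proportional-only model suffices. Standard errors come from the inverse
of a central finite-difference Hessian of OFV/2 at the estimates (observed
Fisher information); a singular or indefinite Hessian sets a
covariance-step flag instead of failing.

Empirical Bayes estimates are the conditional modes at the final estimates;
subjects without observations get exactly zero. Shrinkages are
$100(1-\mathrm{SD}(\hat\eta)/\omega)$ and $100(1-\mathrm{SD}(IWRES))$.

## Covariate selection, bootstrap, diagnostics

Stepwise covariate modeling adds, among the remaining candidates, the one
with the largest significant OFV drop (forward $\alpha=0.05$; degrees of
freedom = number of new parameters, 2 for piecewise-linear) until none
qualifies, then removes the least significant included covariate whose
removal is not significant at the stricter backward $\alpha=0.01$. Ties
break by OFV drop and then candidate order; failed candidate fits are
skipped with a warning and recorded in the trace. The decision logic is
tested in isolation by injecting a mock fitting backend with prescribed
OFVs.

The bootstrap resamples whole subjects with replacement (no
stratification) to the original subject count, refits each replicate
starting from the point estimates, and reports medians and 2.5/97.5
percentile intervals; failed replicates are counted and excluded. A
covariate effect whose interval straddles zero is flagged `unreliable`
— the rationale for dropping a covariate whose bootstrap interval includes
zero from a final model.

The prediction-corrected VPC multiplies every observation (and every
simulated value, through the same code path) by
$\mathrm{median}(PRED_{bin})/PRED_{ij}$, where $PRED$ is the typical
prediction at $\eta=0$. Because all samples here are steady-state draws at
the same time after infusion start, binning defaults to six quantile bins
of $PRED$ (binning by time is available); bins with fewer than two
observations merge into a neighbour with a warning. Simulated replicates
under the fitted model give 95% envelopes of the 5th/50th/95th
prediction-corrected percentiles.

## Toxicity regressions

Adverse events are dichotomized at CTCAE grade ≥ 2 ("severe"); a subject's
gradings across visits collapse by the maximum grade, and subjects without
a record of the queried event type count as non-severe but are flagged
(`observed = FALSE`); collapsing repeated gradings by their maximum is the
conservative convention when no other rule is given. Severe-event
probability follows the logistic model $P = 1/(1+e^{-z})$,
$z = \beta_0 + \beta_1 x$; fits are maximum likelihood (delegated to
`stats::glm`; a brute-force grid oracle cross-checks the estimates in the
tests), inference is Wald, and the effect per 1 cm²/m² of SMI is reported
as an odds ratio $e^{\beta_1}$ with the percent reduction $100(1-OR)$ for
protective effects. Probability bands use the delta method on the logit
scale and are therefore always inside $(0,1)$. One univariable model per
(adverse event, SMI measure) pair is the default, and no multiplicity
adjustment is applied (recorded in the output metadata). The additive
"error term" sometimes written inside the logit of such models has no role
in Bernoulli maximum likelihood and is not a model parameter here.

## The synthetic cohort: what it emulates, and what not

`cohort_spec()` encodes the study population: 111 subjects (75 male / 36
female), age median 64 (35–84), BSA median 1.97 m² (1.47–2.85), the four
SMI measures with their published medians and ranges, BSA-proportional
dosing with a median of 2283 mg/m² (1441–3641) over 24-h infusions, and
1–5 observed cycles per subject with one steady-state TDM draw per cycle.

Only medians and ranges of the covariates are published, so their shapes
are modelled as lognormals with the median as scale and a log-SD chosen so
the expected extremes of 111 draws span the published range, then clamped
to that range. The published table reports a median of 2 observed cycles
but ~3.6 concentrations per subject; with one draw per cycle both cannot
hold simultaneously, so the default cycle distribution
(probabilities 0.08/0.30/0.22/0.20/0.20 for 1–5 cycles) keeps the mode at
2 cycles and yields roughly 370 observations per cohort — the scale that
matters for estimator behaviour. Height is not published (SMI is already
height-normalized); it is drawn from sex-specific normals typical of a
central-European adult cohort (1.76 ± 0.07 m men, 1.63 ± 0.06 m women).
The joint distribution of the four SMI measures is likewise unpublished;
they share one latent "muscularity" factor giving a pairwise log-scale
correlation of 0.8 by default (configurable), motivated by the parallel
behaviour of all four measures in the source analyses. Simulated negative
concentrations (possible under additive error) are set missing with a
warning.

The generator does **not** emulate: dose adjustments between cycles,
longitudinal SMI change, assay censoring at the 86 ng/ml quantification
limit (the reader drops such values; the generator rarely produces them),
correlation between SMI and BSA, or concomitant-therapy structure. Passing
tests therefore demonstrate correct *estimator* behaviour under the
declared generating model, not robustness to those real-data features.

Default adverse-event truths place the severe-event probability at 0.30
for the median patient with slopes $\log(0.15)$ (fatigue vs psoas SMI) and
$\log(0.52)$ (polyneuropathy vs back-muscle SMI) — the published per-unit
reductions of 85% and 48%.

## Validation problem sizes

The test suite exercises: oracle agreement on ≤10-subject fixtures;
recovery of all final-model parameters as medians over 20 replicate
cohorts at full study scale; type-I behaviour of forward inclusion over
200 null cohorts of 50 subjects and power over 100 cohorts with the
reference BSA effect; bootstrap coverage pooled over parameters across 20
cohorts of 30 subjects with 200 replicates each; pcVPC self-consistency at
200 simulations; and logistic effect-size recovery at n = 1000 plus
median-unbiasedness over 50 replicates at n = 111. These sizes were chosen
as the smallest giving stable operating characteristics for each check.

## Known limitations

* Only one structural model (one compartment, linear elimination) — the
  setting the steady-state design can identify.
* The covariance step uses finite differences of an already-approximate
  objective; RSEs inherit that noise (first-order, adequate at the
  reported precision).
* FOCE-style CWRES is a linearization and labelled as such.
* With `omega_eps > 0` the two-dimensional inner problem uses the Laplace
  approximation only.
* The SCM search is greedy, as is conventional; it does not enumerate
  model subsets.
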