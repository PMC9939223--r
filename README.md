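# fupk

Population pharmacokinetics of fluorouracil (5FU) and the influence of the
skeletal muscle index (SMI) on its clearance and toxicity.

## The problem

5FU is dosed by body surface area (BSA), yet its plasma exposure varies
widely between patients. Because 5FU is hydrophilic, body composition —
in particular skeletal muscle mass, summarized as the SMI: the L3-level
muscle cross-sectional area divided by height squared (cm²/m²) — is a
plausible source of that variability, both for pharmacokinetics and for
the probability of severe (CTCAE grade ≥ 2) adverse events.

`fupk` implements the full analysis pipeline for steady-state therapeutic
drug monitoring (TDM) data of 24-h 5FU infusions:

* **Data model & I/O** — a NONMEM-convention rectangular CSV layout
  (`ID, CYCLE, TIME, EVID, MDV, AMT, RATE, DV, SS` + covariate columns),
  the ±205-day CT-to-sampling eligibility window, and the deterministic
  body-composition arithmetic (35–50 HU muscle window on a pixel grid,
  SMI = area/height², AUC = Css × infusion time).
* **Population PK model** — one-compartment, linear elimination, continuous
  infusion at steady state (`Css = R₀/CL`); lognormal interindividual
  variability (IIV) on clearance; multiplicative covariate effects on
  clearance centered at the study medians:

  `CL_i = CL_pop · (1 + θ_BSA(BSA_i − 1.97)) · exp(θ_SMI(SMI_back,i − 3.78)) · exp(η_i)`

  with combined proportional/additive residual error.
* **Estimation** — a marginal-likelihood objective function (OFV, −2 log L
  up to the usual constant) computed by adaptive Gauss–Hermite refinement of
  the Laplace expansion about each subject's conditional mode, with the
  residual variance evaluated at the individual prediction; maximum-likelihood
  fitting, empirical Bayes estimates, η/ε shrinkage, finite-difference
  standard errors, and the likelihood-ratio test (ΔOFV = 3.84 ⇔ p = 0.05
  at 1 df).
* **Covariate selection & robustness** — stepwise covariate modeling
  (forward α = 0.05, backward α = 0.01) over linear, piecewise-linear,
  exponential and power parametrizations, and a non-parametric
  subject-resampling bootstrap with percentile intervals and an
  "CI includes zero" reliability flag.
* **Diagnostics** — prediction-corrected visual predictive checks (pcVPC)
  and goodness-of-fit tables (PRED/IPRED/IWRES/CWRES).
* **Toxicity** — logistic regression of severe-adverse-event probability on
  SMI measures with odds ratios per 1 cm²/m², Wald confidence intervals and
  delta-method probability bands.
* **Synthetic cohorts** — a generator emulating the study population
  (111 subjects, ~370 steady-state samples over 1–5 cycles, published
  covariate medians/ranges) so that every stage is testable end to end
  without patient data.

## Worked example

Simulate a study-scale cohort under the reference (final-model) parameter
set, refit the model, and inspect the estimates:

```r
library(fupk)

cohort <- generate_cohort(cohort_spec(), seed = 42)
sim    <- simulate_concentrations(cohort, fu_reference_model(), seed = 7)

init <- pop_model(
  cl_pop = 150,
  effects = list(
    covariate_effect("bsa", "linear_proportional", 0, center = 1.97),
    covariate_effect("smi_back", "exponential", 0, center = 3.78)
  ),
  omega_cl = 0.3, sigma_prop = 0.3
)
fit <- fit_pk(sim, init)
tidy(fit)
#> # A tibble: 7 × 6
#>   term           estimate std.error rse_percent fixed boundary
#>   <chr>             <dbl>     <dbl>       <dbl> <lgl> <lgl>
#> 1 cl_pop         230.        5.73          2.50 FALSE FALSE
#> 2 theta_bsa        0.759     0.0760       10.0  FALSE FALSE
#> 3 theta_smi_back   0.0511    0.0133       25.9  FALSE FALSE
#> 4 omega_cl         0.205     0.0207       10.1  FALSE FALSE
#> 5 sigma_prop       0.217     0.0104        4.77 FALSE FALSE
#> 6 v               46.1      NA            NA    TRUE  FALSE
#> 7 omega_v          0.482    NA            NA    TRUE  FALSE
```

The simulation truth (CL 223 L/h, BSA effect 0.794, SMI effect 0.0570,
IIV 20.9 %CV as ω = 0.207, proportional error 0.214) is recovered within
sampling error; `glance(fit)` additionally reports the OFV, convergence,
and the η/ε shrinkage (the volume-of-distribution random effect is 100%
shrunk with steady-state-only sampling, which is why V is fixed at 46.1 L).

Toxicity side, per 1 cm²/m² of psoas SMI:

```r
ae  <- simulate_adverse_events(cohort, reference_ae_truth(), seed = 9)
df  <- merge(dichotomize_grades(ae, "fatigue"), ae$subjects)
tox <- fit_logistic(df, "outcome", "smi_psoas")
odds_ratio(tox, "smi_psoas")
#> # A tibble: 1 × 7
#>   covariate delta    or conf.low conf.high percent_change   p.value
#>   <chr>     <dbl> <dbl>    <dbl>     <dbl>          <dbl>     <dbl>
#> 1 smi_psoas     1 0.103   0.0348     0.306           89.7 0.0000420
```

i.e. each additional cm²/m² of psoas muscle multiplies the odds of severe
fatigue by ~0.10 in this 111-subject draw — consistent, within the sampling
error of a single small cohort, with the simulated odds ratio of 0.15 (an
85% reduction per unit).

Diagnostics: `autoplot(pc_vpc(fit, sim, n_sim = 1000, seed = 1))` draws the
prediction-corrected VPC; `plot_gof(fit, sim)` the usual goodness-of-fit
panels; `scm()` and `bootstrap_pk()` run covariate selection and the
resampling analysis.

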