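---
title: "Model, estimation and design choices in mgppk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimation and design choices in mgppk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgppk)
```

mgppk models total serum magnesium in women with preeclampsia receiving
intravenous magnesium sulfate as loading + maintenance infusions. This
vignette records the model, the numerical machinery, and the design
choices made where the problem was genuinely open — the level of detail a
maintainer needs to trust or change the code.

## Structural model and units

Drug disposition is one-compartment with zero-order infusion input and
first-order elimination. The analytic solution is used throughout — during
an infusion at rate $R_0$ begun at $t_0$ the above-baseline concentration
is $(R_0/CL)(1-e^{-k(t-t_0)})$ with $k = CL/V$; after the infusion end the
end-of-infusion value decays as $e^{-k(t-t_e)}$ — and multi-event
schedules superpose linearly. The test suite verifies the closed form
against an adaptive ODE integration to $10^{-6}$ relative error and checks
mass balance ($AUC \times CL$ = administered amount, 0.1%).

Internal units are milligrams of elemental magnesium per litre and hours.
The reporting unit is mmol/L (1 mmol/L = 24.305 mg/L). Doses are labelled
grams of salt, converted through a configurable `salt_factor`; the default
assumes the heptahydrate (MgSO₄·7H₂O, MW 246.47, 98.6 mg Mg per labelled
gram), which is the form dispensed for intravenous use and — decisive here
— the only convention under which the fitted parameters, the observed
concentration range and the residual SD (3.65, plausible in mg/L, absurd
in mmol/L) are mutually consistent: a 10 g maintenance over 6.7 h at
typical clearance then yields a steady state near baseline + 2 mmol/L,
i.e. the bottom of the therapeutic window.

Total concentration is a constant individual baseline plus the drug model.
How the original analysis handled endogenous magnesium is not stated; the
`baseline` policy of `model_spec()` chooses between a per-subject measured
value (`"data"`, the default — pre-treatment magnesium is observed in this
design), a global constant, or zero. The day-2 dose is placed 24 h after
the day-1 loading start (configurable); time zero is the start of the
day-1 loading dose.

## Covariate model and the normalization constants

Continuous covariates enter as power terms $(x/\mathrm{ref})^{\theta}$,
binary ones as proportional terms $(1+\theta x)$ with signed coefficients,
so the final model reads

$$CL = tvCL\,(CCR/\mathrm{ref})^{0.39}(BMI/\mathrm{ref})^{-0.54}
       (1-0.16\,furo)\,e^{\eta_{CL}},\qquad
  V = tvV\,(1-0.25\,furo)\,e^{\eta_V}.$$

The published equation prints both normalization constants as 51 — which
equals the cohort size, while conventional practice normalizes at the
covariate median (CCR ≈ 182 ml/min, BMI ≈ 29 kg/m²). The constant is
structurally inert: rescaling the reference and compensating the typical
value leaves every prediction unchanged (a tested invariance), but it
decides what $tvCL$ *means*. Two observations favour the median reading:
the typical clearance 2.98 L/h is discussed as the cohort-typical value
(and compared with literature typical clearances of 1.38–5.00 L/h), and
the dose-optimization findings only make sense if the median patient's
clearance is 2.98 L/h — under "/51" the median patient would clear at
~6.6 L/h and no candidate regimen could reach the therapeutic window at
all. `final_model_spec()` therefore keeps the printed 51 as the default
(with `ref_ccr`/`ref_bmi` overrides), while every analysis in this package
— recovery experiments, dose optimization — uses the median-referenced
parameterization with the published values as truth. A practical side
benefit: under "/51" the regressor $\log(BMI/51)$ is nearly constant
across the cohort, putting $(tvCL, \theta_{BMI})$ on a collinear ridge
that inflates and skews their finite-sample spread; the median reference
removes the ridge.

## FOCE estimation

The marginal likelihood is approximated subject-by-subject. For subject
$i$ with diagonal $\Omega$ (the reported model has no covariance term) the
objective is

$$OFV = \sum_i \left[ -2\log p(y_i \mid \hat\eta_i)
        - 2\log p(\hat\eta_i) + \log\det(G_i^T\Sigma_i^{-1}G_i + \Omega^{-1})
        - q\log 2\pi \right]$$

with $\hat\eta_i$ the conditional mode of the joint density and $G_i$ the
sensitivity of the predictions to $\eta$ at the mode. The inner mode
search is a damped Gauss–Newton iteration, vectorized across subjects,
using analytic derivatives of the infusion solution with respect to
$\log CL$ and $\log V$; steps are halved per-subject until the exact joint
objective decreases, and the iteration stops when the largest step falls
below $10^{-8}$. Modes are warm-started across outer iterations. Because
the Gauss–Newton curvature $G^T\Sigma^{-1}G + \Omega^{-1}$ is evaluated at
the mode with $\Sigma$ at the conditional prediction, the objective is
FOCE with interaction when the residual model depends on the prediction
(proportional/combined) and plain FOCE for additive error, where
interaction is immaterial. On small cohorts the objective agrees with
exact tensor Gauss–Hermite quadrature of the marginal likelihood to within
1% (tested); the quadrature exists only as a test oracle, never as a
production path.

The outer problem is solved by `nlminb` on a transformed scale: log for
typical values, variances and residual SDs; `atanh` for proportional
coefficients (keeping $1+\theta x > 0$ without constrained solvers); the
identity for power exponents. Convergence uses a relative objective
tolerance of $10^{-8}$ with at most 500 outer iterations. Setting an
`omega2` entry to zero fixes that random effect out of the model (with
both fixed and one subject the fit reduces to least squares — tested
against an independent minimizer); `fix_sigma = TRUE` freezes the residual
parameters. Standard errors are square roots of the diagonal of
$2H^{-1}$, $H$ the central-difference Hessian of the OFV at the optimum on
the natural scale, with relative steps of $10^{-3}$; AIC $=$ OFV $+2p$ and
BIC $=$ OFV $+p\log n$ hold by construction. Empirical-Bayes shrinkage is
$100(1-\mathrm{SD}(\hat\eta)/\omega)$, clipped at zero with a warning.

## Stepwise covariate modeling

Forward selection fits the current model plus each remaining candidate and
accepts the largest OFV drop if it reaches $\chi^2_1(0.01) = 6.63$
(inclusive); backward elimination then removes, smallest rise first, any
added effect whose removal costs less than $\chi^2_1(0.001) = 10.83$. One
effect moves per step with 1 df each; ties break by candidate label.
Candidates whose refit fails to converge are skipped and logged, and the
full decision trace (candidate, OFVs, ΔOFV, decision) is exportable so
every decision is reproducible from the logged numbers. The default
candidate map offers CCR, BMI, age and albumin as power terms referenced
at the dataset median and furosemide, labetalol, nifedipine and ADR as
proportional terms, each on both CL and V — whether the original analysis
screened both parameters for every covariate is not stated, so the list is
an argument. On a single 51-subject replicate only the strongest effect
(CCR on CL) reliably clears these thresholds; detecting the full published
structure needs richer designs (the operating-characteristics tests use
n = 200 with 8–12 samples), which is worth remembering when reading any
single SCM trace at the study's size.

## Diagnostics

CWRES uses the standard FOCE linearization: per subject the residual
$y - (f(\hat\eta) - G\hat\eta)$ is whitened by
$G\,\Omega\,G^T + \Sigma$. With no random effects it collapses exactly to
the standardized residual (tested); under a well-specified model it is
approximately standard normal, and the suite checks mean, SD and the
"within ±2" fraction on synthetic fits. The bootstrap resamples subjects
with replacement (clones get fresh IDs), refits, and reports per-parameter
medians and 2.5/97.5 percentiles; one master seed spawns one sub-seed per
replicate index, so results do not depend on subject labels. The VPC
simulates the fitted model at the observed design (covariates, doses,
sampling times), bins by nominal sampling time — the design is
nominal-time structured, so each of 0/4/5/12 h is its own bin — and
reports observed 5/50/95 percentiles against the 2.5/50/97.5 bands of the
simulated percentiles, both percentile conventions mentioned in the source
material; the fraction of observations inside their own simulated
2.5–97.5 interval summarizes calibration and is invariant to the
concentration unit (tested).

## Dose optimization

`simulate_population()` draws $\eta \sim N(0,\Omega)$ per individual and
evaluates noise-free profiles: residual error is assay noise, not biology,
so attainment is judged on model-predicted concentrations (a `residual`
switch includes it). The baseline 0.76 mmol/L is added by default —
without it the window is unreachable at the stated doses, which is itself
a documented sanity finding. PTA is the fraction of individuals inside the
closed window [2.0, 3.5] mmol/L at hourly checks; "appropriate" means
strictly more than 90% at every hour from 4 through 8 (the "after the
fourth hour" rule, read inclusively on hours 4–8).

One limitation surfaced by this reimplementation: within the 8-h horizon
the printed parameters and doses cannot push any typical patient above
3.5 mmol/L under the estimation-consistent salt factor, so the reported
toxicity of the 15 g maintenance regimens cannot be a within-first-day
phenomenon of the printed model. It does appear at the regimen's steady
state — relevant because dosing is repeated daily — where the 15 g rates
exceed 3.5 mmol/L in 13 of 18 covariate cells and the 10 g rates in 1 of
18 (computed by `analysis/05_dose_optimization.R` and asserted by the
acceptance suite). The qualitative orderings are unambiguous either way:
furosemide raises the whole profile (both CL and V reduced), and the 5 g
loading dose reaches the window hours earlier than 2.5 g.

## The synthetic-study generator

`generate_study()` emulates the observed design: 51 subjects; day-1 5 g
loading with duration drawn uniformly in 0.5–2 h (set by the clinician in
the study, so a range, not a constant) followed immediately by 10 g over
6–8 h; day-2 10 g over 6–8 h starting at 24 h; samples at 0/4/5/12 h after
the day-2 dose start. The pre-dose sample is always taken and each later
one is kept with probability 0.95, reconciling the reported "two to four
samples" with the reported totals (199/51 ≈ 3.9 per subject); a minimum of
two is enforced. Covariates are anchored to the cohort table: CCR normal
(182.18, 67.15) truncated above 30 ml/min; BMI and baseline magnesium
log-normal matched to their reported quartiles; furosemide
Bernoulli(0.3137); nuisance covariates (age, gestational age, albumin,
calcium, labetalol, nifedipine, ADR, twins) matched to the same table.
What the generator does *not* emulate: covariate correlations (everything
is drawn independently, whereas furosemide use in practice accompanies
renal impairment and high BMI), time-varying covariates, dropout linked to
clinical state, assay censoring, and repeat days beyond day 2. Passing
recovery tests therefore show that the estimator inverts the stated
generative model at the study's design — not that the model is correct for
real cohorts.

## Problem sizes and known limitations

The test suite runs the recovery experiment at its natural size (50
replicates of 51 subjects) and the SCM operating characteristics at 20
replicates (n = 200 rich for power, n = 51 for type-I); the bootstrap and
VPC unit tests use reduced sizes (B = 60, 400 simulations) with the
reference sizes (B = 1000, 1000 simulations) exercised through
configuration defaults. The estimator's known small-sample behaviour on
this sparse design: ω²_CL medians sit ~15% below truth (within the
declared tolerance; a familiar FOCE effect when most subjects contribute
four points), ω²_V is weakly identified (high shrinkage), and the
furosemide-on-CL coefficient has large per-replicate spread, consistent
with the published bootstrap CVs. Multi-compartment kinetics, nonlinear
elimination, intramuscular administration, off-diagonal Ω and SAEM/MCMC
estimation are out of scope.
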