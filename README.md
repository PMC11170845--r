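# mgppk

Population pharmacokinetics and dose optimization of intravenous magnesium
sulfate for seizure prophylaxis in preeclampsia.

Magnesium sulfate is the anticonvulsant of choice in preeclampsia, but it
has a narrow therapeutic margin (2.0–3.5 mmol/L total serum magnesium) and
most empirical regimens leave many patients below it. This package
implements the full population-PK workflow for the Chinese loading +
maintenance regimen (day 1: 5 g over 0.5–2 h then 10 g over 6–8 h;
day 2+: 10 g over 6–8 h), for pharmacometricians and clinical
pharmacologists who want to refit, stress-test or extend the model. A
synthetic-study generator emulating the observed design (51 subjects,
~199 serum samples at 0/4/5/12 h after the day-2 dose) makes every stage
runnable without patient data.

## The model

Serum magnesium follows a one-compartment model with zero-order infusion
input and first-order elimination, on top of an endogenous baseline
(≈ 0.76 mmol/L). Above-baseline concentration during an infusion at rate
*R₀* started at *t₀* is (R₀/CL)(1 − e^(−k(t−t₀))), *k* = CL/V, decaying
exponentially after the infusion ends; multi-day schedules superpose
linearly. Individual parameters follow the final covariate model

    CL_i = tvCL · (CCR_i/ref)^0.39 · (BMI_i/ref)^−0.54 · (1 − 0.16·furosemide_i) · exp(η_CL,i)
    V_i  = tvV · (1 − 0.25·furosemide_i) · exp(η_V,i)

with tvCL = 2.98 L/h, tvV = 25.07 L, η ~ N(0, ω²) (ω²_CL = 0.082,
ω²_V = 0.023) and additive residual error (SD 3.65 mg/L). Estimation is
FOCE: each subject's random-effect mode is found by a damped Gauss–Newton
search with analytic sensitivities, and the marginal −2 log-likelihood is
approximated by the Laplace value with Gauss–Newton curvature. Covariates
are selected by stepwise forward inclusion (ΔOFV ≥ 6.63, p < 0.01) and
backward elimination (ΔOFV ≥ 10.83, p < 0.001); diagnostics cover
PRED/IPRED/CWRES, a subject-resampling bootstrap and a visual predictive
check. Dose optimization simulates 1000 individuals per covariate cell
(CCR 140/175/213 ml/min × BMI 27/29/33 kg/m² × furosemide) under four
candidate regimens and scores the probability of sitting inside
2–3.5 mmol/L hourly; a regimen is appropriate when that probability
exceeds 90% at every hour from 4 to 8.

## Worked example

```r
library(mgppk)

spec <- final_model_spec(ref_ccr = 182.18, ref_bmi = 29.13)
d <- generate_study(spec = spec, seed = 1)    # 51 subjects, 197 observations
fit <- foce_fit(d, spec)
print(fit)
```

```
FOCE fit: 51 subjects, 197 observations
OFV 1189.340  AIC 1207.340  BIC 1236.889  (9 parameters, converged: TRUE)
         estimate     se   cv_pct
tvCL       2.7012 0.1316   4.8736
tvV       23.4276 1.0992   4.6920
...
eta shrinkage (%): CL 8.8, V 62.4
```

The single-replicate estimates scatter around the generating values (tvCL
2.70 vs 2.98 here); the medians across 50 replicates are unbiased —
`analysis/06_recovery.R` prints median tvCL 2.978 L/h, tvV 25.01 L and
relative biases below 8% for every fixed effect. Dose simulation:

```r
tr <- published_estimates()
conc <- simulate_population(tr$theta, tr$omega2,
                            cell = list(CCR = 175, BMI = 29, FURO = 1),
                            reg = standard_regimens()$L5_M10, n = 1000,
                            seed = 1, spec = final_model_spec(175, 29))
pta(conc)          # hourly fraction of individuals inside 2-3.5 mmol/L
```

The numbered scripts under `analysis/` run the complete workflow
(simulate → fit → covariate selection → bootstrap/VPC/GOF → Monte Carlo
dose optimization → recovery experiment) and write their tables under
`results/`.

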