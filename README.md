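# spautolog

Auto-logistic spatial modelling of binary health outcomes in geocoded
patient cohorts.

## The problem

In-hospital deaths of EMS-transported patients are not spatially random:
patients from the same neighbourhood share ambulance access,
socio-economic conditions and primary care, so nearby patients' outcomes
are correlated. An ordinary logistic regression of death on patient-level
covariates ignores this and both misstates uncertainty and leaves spatial
risk unexplained. The auto-logistic model (Besag) captures the dependence
with a single extra covariate, the **autocovariate**

```
A_i = Σ_j w_ij y_j / Σ_j w_ij,   w_ij = 1/d_ij  for 0 < d_ij ≤ r,
```

the inverse-distance-weighted average of the observed outcomes of patient
i's neighbours within a distance band of radius r, so that

```
logit P(Y_i = 1) = β'x_i + γ A_i .
```

Fitting this by ordinary maximum likelihood with the observed-outcome
autocovariate is the maximum-pseudolikelihood estimator of the underlying
autologistic random field; γ measures, on the log-odds scale, how strongly
individual risk follows the mortality of the surroundings.

The package implements the full workflow for this analysis —
distance-band inverse-distance weights, the autocovariate, global and
local Moran's I with permutation inference, logistic and auto-logistic
fits with odds-ratio reporting, the two-stage P < 0.25 screening
procedure, AIC/AUC model comparison, residual spatial diagnostics, and
CSV/GeoJSON exports — plus a Gibbs-sampled synthetic cohort generator
that emulates a one-year urban stroke registry (≈1170 address-geocoded
patients, ~14% mortality), so that every stage is testable although such
registries are private. The audience is epidemiologists and
biostatisticians analysing geocoded patient-level binary outcomes.

## Worked example

```r
library(spautolog)

ds <- generate_dataset(sim_config(seed = 1))   # synthetic cohort, n = 1170
report <- run_pipeline(ds$cohort, radius = 150, seed = 3)
report
```

```
Spatial mortality analysis report
  n = 1170, mortality 16.2%
  screened covariates: age, accessibility_rate, transport_time, revealed_access, screening_time, distance_to_hospital, los, triage, final_dx 
  logistic:      AIC 992.7  AUC 0.675  residual Moran p 0.061
  auto-logistic: AIC 986.5  AUC 0.681  residual Moran p 0.969
  gamma (autocovariate): 0.92  OR 2.51 (1.36-4.63)
  preferred model: auto-logistic
```

Reading the report: the univariate screen kept nine candidate risk
factors; both multivariable models were fitted on them. The auto-logistic
model is preferred by AIC (986.5 vs 992.7), its residuals show no
remaining positive spatial autocorrelation (one-sided permutation Moran
p = 0.97, against p = 0.06 for the ordinary model's residuals), and the
spatial coefficient is recovered near its simulated value γ = 1
(γ̂ = 0.92, odds ratio 2.51 per unit of neighbourhood mortality). The full
coefficient table mirrors the conventional "OR (95% CI)" presentation:

```r
print(report$fit_autologistic)
```

```
Auto-logistic (pseudolikelihood) regression: death ~ age + accessibility_rate + ... + autocovariate 
  n = 1170 (189 events)   logLik = -482.27   AIC = 986.5
                 term      OR (95% CI)       p
          (Intercept) 0.10 (0.03-0.34) 2.4e-04
                  age 1.02 (1.01-1.03) 2.6e-03
   accessibility_rate 0.96 (0.94-0.99) 2.1e-03
       transport_time 1.00 (0.95-1.05) 9.6e-01
      revealed_access 1.01 (0.97-1.06) 5.7e-01
       screening_time 0.34 (0.16-0.73) 5.6e-03
 distance_to_hospital 0.95 (0.89-1.01) 7.3e-02
                  los 1.03 (1.01-1.04) 4.6e-05
       triagelevels34 2.07 (1.49-2.89) 1.7e-05
          final_dxyes 1.47 (1.04-2.08) 3.1e-02
        autocovariate 2.51 (1.36-4.63) 3.3e-03
```

Per-year age, per-day length of stay and triage levels 3–4 raise the odds
of death; each additional ambulance per million inhabitants lowers them —
the effect structure the generator was parameterized with. A per-patient
autocovariate map layer (GeoJSON) and tidy CSV/JSON model cards are
written when `run_pipeline(..., out_dir = )` is given, and a thin command
line (`inst/exec/spautolog`) exposes `simulate`, `describe`, `fit`, `run`
and `map` subcommands.

The methods vignette (`vignettes/autologistic-methods.Rmd`) documents the
model, the permutation tests, the generator's design and its deliberate
simplifications.

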