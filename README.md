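# vancopk

Population pharmacokinetics and renal dose tailoring of vancomycin in R.

Vancomycin is a narrow-therapeutic-index antibiotic cleared almost entirely
by the kidney; keeping the steady-state trough concentration inside the
10–20 mg/l window requires adjusting the dose to the patient's renal
function. `vancopk` implements the full nonlinear mixed-effects workflow a
pharmacometrician would apply to sparse therapeutic-drug-monitoring data
from an adult surgical population, and uses the fitted model to tailor
doses by creatinine clearance (CRCL). It is written tidyverse-style:
data-frame-first functions, tibble outputs, `tidy()`/`glance()`/`augment()`
methods and `autoplot()` diagnostics.

## The model

Concentrations follow a one-compartment model with first-order elimination
after intravenous infusion (a two-compartment option is included).
Individual parameters combine typical values, covariate factors and
exponential between-subject variability (BSV):

```
CL_j = θ_CL · (1 + θ_CRCL (CRCL_j − 101.15)) · (1 − θ_WT (WT_j − 75)) · e^{η1j}
V_j  = θ_V · e^{η2j},      η ~ N(0, ω²),   y_ij = f_ij + ε_ij
```

Estimation is by the first-order conditional method with interaction
(FOCE-I), authored in this package with a compiled (RcppArmadillo) engine
and an independent pure-R reference implementation: per subject the
conditional mode η̂ of the penalized objective is located by a damped
Newton search, and the −2 log-likelihood contribution is the linearized
approximation `log|V| + r'V⁻¹r` with `V = GΩG' + diag(g(η̂))`,
`r = y − f(η̂) + Gη̂`. On top of the fit the package provides:

- stepwise covariate modeling (forward ΔOFV ≥ 3.84, backward ≥ 6.63),
- nonparametric bootstrap (subject resampling) and visual predictive
  checks (90% prediction bands of binned percentiles),
- conditional weighted residuals (CWRES), EBEs and goodness-of-fit tables,
- closed-form steady-state trough simulation and dose tailoring against a
  target trough concentration range (TTCR),
- a synthetic-cohort generator emulating the study design (58 subjects,
  ~3 samples each, Cockcroft–Gault CRCL) so everything is testable
  without patient data.

## Worked example

```r
library(vancopk)

model <- vanco_final_model()   # reported final model
model
#> <pk_model> one_cmt
#>   theta: cl = 2.45, v = 22.6
#>   BSV %CV: cl = 11.3, v = 22.8
#>   error: additive (add = 3.07 mg/l)
#>   relations:
#>     cl ~ crcl [linear_centered] value 0.0046 center 101.15
#>     cl ~ wt [linear_centered] value -0.011 center 75

# simulate a study-like cohort and refit it
ds <- simulate_study(n_subjects = 58, seed = 11)
fit <- fit_foce(ds, model)
glance(fit)
#> # A tibble: 1 × 6
#>     ofv  npar n_subjects n_obs converged boundary
#>   <dbl> <int>      <int> <int> <lgl>     <lgl>
#> 1  740.     7         58   188 TRUE      FALSE
tidy(fit)[1:4, 1:2]
#> # A tibble: 4 × 2
#>   term      estimate
#>   <chr>        <dbl>
#> 1 tvcl       2.58
#> 2 tvv       23.1
#> 3 b_cl_crcl  0.00445
#> 4 b_cl_wt   -0.00976

# steady-state troughs for 1,000 mg q12h across renal strata
simulate_troughs(model, crcl = c(20, 60, 100, 140), dose = 1000,
                 n = 1000, seed = 101)[, c("crcl", "trough_mean",
                                           "trough_sd", "fraction_in_ttcr")]
#> # A tibble: 4 × 4
#>    crcl trough_mean trough_sd fraction_in_ttcr
#>   <dbl>       <dbl>     <dbl>            <dbl>
#> 1    20        35.9      6.82            0.008
#> 2    60        24.0      5.30            0.227
#> 3   100        17.2      4.50            0.695
#> 4   140        12.7      3.69            0.728

# tailor the dose for a patient with CRCL 20 ml/min
tailor_dose(model, crcl = 20, n = 1000, seed = 220)$selected_dose
#> [1] 400
```

The fit recovers the generating typical values (`tvcl` 2.58 vs 2.45 L/h,
`tvv` 23.1 vs 22.6 L on this seed); the 1,000-mg troughs show accumulation
in renal impairment (mean 35.9 mg/l at CRCL 20, far above the window) and
the tailored 400-mg dose brings that stratum back inside 10–20 mg/l.

`run_pipeline()` chains fit → SCM → bootstrap → VPC → dosing from a YAML
configuration and writes CSV tables plus a JSON run record that makes the
whole run reproducible from its seed.

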