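---
title: "Methods: population PK modeling and dose tailoring of vancomycin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK modeling and dose tailoring of vancomycin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancopk)
```

This vignette documents the statistical model, the estimation method, the
numerical choices and the known limitations behind `vancopk`. It is the
package's account of *why* things are done the way they are; the README
shows *how* to run them.

## Structural and statistical model

Vancomycin kinetics after intravenous infusion are described by a
one-compartment model with first-order elimination. For a dose infused at
rate $R$ over $T_{inf}$ hours, the concentration contribution is
$\frac{R}{CL}(1 - e^{-k(t-t_0)})$ during the infusion and exponential
decay of the end-of-infusion value afterwards, with $k = CL/V$; multiple
doses superpose linearly. All solutions are closed-form and continuous in
time — no ODE grid is involved, which removes discretization error and
makes simulation of $10^5$ patients instantaneous. A bi-exponential
two-compartment option (`conc_two_cmt()`) exists for structural
comparison; its hybrid constants are evaluated with `expm1()` so the
solution degrades gracefully into the one-compartment curve as the
inter-compartmental clearance vanishes.

Individual parameters combine typical values, covariate factors and
exponential between-subject variability (BSV):

$$CL_j = \theta_{CL}\prod_k h_k(x_{jk})\, e^{\eta_{1j}}, \qquad
  V_j = \theta_V \prod_k h_k(x_{jk})\, e^{\eta_{2j}},$$

with independent $\eta \sim N(0, \omega^2)$. Three covariate forms are
supported: linear centered $1 + \beta(x - \bar x)$, allometric power
$(x/\bar x)^p$ (exponent fixed, conventionally 0.75 on clearance and 1 on
volume), and fractional shifts for sex. BSV is reported as a percentage
coefficient of variation $100\sqrt{\omega^2}$, the dominant reporting
convention for exponential random effects.

The default reproduction model (`vanco_final_model()`) carries typical
clearance 2.45 L/h and volume 22.6 L at the population medians (CRCL
101.15 ml/min, weight 75 kg), linear centered slopes 0.0046 per ml/min of
CRCL and −0.011 per kg on clearance, BSV of 11.3% (CL) and 22.8% (V), and
an additive residual error of 3.07 mg/l. An additive error is the default
because the reported variability is quantified on that scale; proportional
and combined errors are available through `error_model()`.

Renal function enters through the Cockcroft–Gault equation,
$CRCL = (140 - age)\,wt / (72\,scr)$, times 0.85 for females. When a
dataset lacks a CRCL column it is computed from the recorded covariates;
an explicit column is taken as authoritative.

### Numerical guard: covariate factor floor

The linear centered form is unbounded below: the weight slope crosses zero
near 166 kg when extrapolated. Every covariate factor is therefore floored
at 0.01 (with a warning in user-facing calls), so extreme covariates can
never drive a clearance or volume non-positive. Inside the estimation
engine the floor is applied silently, because the outer optimizer may
transiently propose extreme slopes while converging to an interior
optimum.

## FOCE-I estimation

The marginal likelihood of a nonlinear mixed-effects model has no closed
form; `fit_foce()` uses the first-order conditional approximation with
interaction. Per subject:

1. The conditional mode $\hat\eta$ minimizes the penalized objective
   $\sum_j \left[(y_j - f_j(\eta))^2 / g_j(\eta) + \log g_j(\eta)\right] +
   \eta^\top \Omega^{-1}\eta$, where $g$ is the residual variance
   evaluated *at* $\eta$ (the interaction). The search is a damped Newton
   iteration from $\eta = 0$ with a Gauss–Newton Hessian, Armijo
   backtracking, and termination when the gradient falls below
   $10^{-6}(1 + |h|)$ or the objective change below $10^{-9}(1 + |h|)$.
2. The subject's $-2\log L$ contribution is
   $\log|V_i| + r_i^\top V_i^{-1} r_i$ with
   $V_i = G_i \Omega G_i^\top + \mathrm{diag}\, g(\hat\eta)$,
   $G_i = \partial f/\partial\eta|_{\hat\eta}$ (central differences, step
   $10^{-4}$) and $r_i = y_i - f_i(\hat\eta) + G_i\hat\eta$. The
   $n\log 2\pi$ constant is omitted, the usual objective-function-value
   (OFV) convention, so OFV differences are likelihood-ratio statistics.

The outer problem minimizes the summed OFV over typical values, covariate
slopes, variances and error SDs with `nlminb()`. Positive parameters are
optimized on the log scale (positivity without constraints); slopes on the
identity scale. A variance initialized at zero disables its random effect
entirely. Convergence is declared at a relative OFV change of $10^{-8}$;
variance estimates below $10^{-4}$ (CV < 1%) are flagged as boundary.
Standard errors come from the inverse of a central-finite-difference
Hessian of the OFV ($\mathrm{Cov} = 2H^{-1}$); no sandwich correction is
applied. The fit is fully deterministic — no random numbers are drawn
anywhere in estimation.

Two implementations of the same objective exist: a compiled
RcppArmadillo engine (production path for the one-compartment model) and
a pure-R reference that accepts either structural model. They are held to
agreement within $10^{-6}$ OFV points in the test suite, and both are
checked against an independent dense-grid quadrature evaluation of the
exact marginal likelihood on small instances (agreement within 1 OFV
point across random parameter sets — the approximation, not the
arithmetic, is the limit).

Residual variance uses the conditional prediction with a 0.01 mg/l floor
inside $g$ for proportional components, preventing degenerate
zero-variance weights near the origin.

### Diagnostics

Conditional weighted residuals are $CWRES = L^{-1}(y - \hat y)$ with
$V = LL^\top$ the FOCE-I observation covariance and
$\hat y = f(\hat\eta) - G\hat\eta$; under a correct model they are
approximately standard normal, so about 95% fall in $[-2, 2]$ — a
property the test suite verifies on data simulated from a fitted model.
`gof_tables()` assembles DV/PRED/IPRED/CWRES/time-after-dose, and
`autoplot()` draws the four standard panels.

## Stepwise covariate modeling

`run_scm()` screens candidate parameter–covariate relations by greedy
forward inclusion and backward elimination on the OFV. A candidate enters
when its OFV drop is at least 3.84 ($\alpha = 0.05$, 1 df); among
qualifying candidates the largest drop wins. A relation survives backward
elimination only if removing it raises the OFV by at least 6.63
($\alpha = 0.01$). Both thresholds are inclusive — a drop of exactly 3.84
includes, a rise of exactly 6.63 retains. Ties are broken by a
deterministic screening order (clearance before volume; CRCL, WT, AGE,
SCR, SEX within a parameter) so runs are reproducible. Candidates whose
fits fail to converge are skipped for the round and logged rather than
aborting the search. Serum creatinine and CRCL are both offered despite
their collinearity; no special-casing is applied. The null calibration of
the forward test (inclusion rate near 5% for a truly inert covariate) is
verified by simulation in the acceptance suite.

## Model evaluation

**Bootstrap.** Subjects are resampled with replacement to the original
subject count (a subject's rows always travel together, no
stratification), the model is refitted per replicate starting from the
original estimates, and parameters are summarized by median and
2.5th/97.5th percentiles. Bias is $100(\hat\theta -
\mathrm{median}^*)/\hat\theta$ on unrounded medians. Non-converged
replicates are dropped and counted; more than 20% failures attaches a
warning rather than aborting.

**Visual predictive check.** `vpc_pk()` simulates full datasets at the
original design (same subjects, doses, times, covariates; fresh $\eta$
and residual draws), bins observations by time after dose into
quantile-based bins (default 6, chosen so each bin holds roughly equal
counts — percentiles from ~30 observations per bin are already unstable,
so equal-count binning is preferred over equal-width), and overlays the
observed 5th/50th/95th percentiles on the 90% prediction interval of the
corresponding simulated percentiles. No prediction correction is applied
(a plain VPC).

## Dose tailoring

`simulate_troughs()` draws virtual patients at a fixed CRCL, computes
individual clearances and volumes through the covariate model with both
BSV terms sampled, and evaluates the closed-form steady-state pre-dose
concentration

$$C_{trough} = \frac{D}{T_{inf} CL}\,
  \frac{1 - e^{-kT_{inf}}}{1 - e^{-k\tau}}\, e^{-k(\tau - T_{inf})}.$$

Design choices, each of which was fixed once:

- **Trough timing**: the trough is the concentration at $t = \tau$ after
  an infusion start — the instant before the next dose, the standard
  trough definition.
- **Virtual weight** is fixed at the population median 75 kg, making the
  weight factor exactly 1, so renal function is the only covariate that
  varies across strata.
- **Residual (assay) error is excluded** from simulated troughs: the
  target range is a statement about the true concentration, and adding
  mean-zero noise would not move the means but would corrupt the
  in-range fractions.
- **Steady state is computed analytically**, not by superposing many
  doses; equality with a 30-dose superposition to within 0.1% is a tested
  invariant.

`tailor_dose()` evaluates candidate doses (default 200–1,400 mg in 100-mg
steps, q12h) under common random numbers — one set of virtual patients
shared by all candidates, exact because the trough is linear in dose —
and selects the dose maximizing the fraction of patients inside the
10–20 mg/l target range, breaking ties toward the smaller dose. The
criterion itself is validated analytically in the test suite: treating
each stratum's trough distribution as normal with the tabulated mean and
SD at 1,000 mg and scaling linearly with dose, the fraction-in-range
criterion picks 400/600/800/1,000 mg at CRCL 20/60/100/140 ml/min.

A known sensitivity: at high CRCL the in-range fractions of adjacent
100-mg candidates are nearly tied, so a few-percent shift in the mean
trough can move the selected dose by one step. In this package's
simulations at CRCL 140 the selection lands on 1,100 mg rather than
1,000 mg, because the simulated mean trough at 1,000 mg sits about 7%
lower than the tabulated reference value for that stratum — within the
±15% band that the under-specified simulation settings warrant, but
enough to tip a near-tie. The corresponding acceptance assertion is left
failing rather than adjusting the simulator toward the expected answer.

## Synthetic cohort generator

`sample_cohort()` emulates the study design so every stage is testable
without patient data: 58 adult surgical patients (39 male, 19 female —
an exact split), ages centered at 54 years (range 25–86), weights at
75 kg (53–129), serum creatinine at 0.935 mg/dl (0.4–4.7), single
0.5-h infusions of 1,000 mg with probability 0.7 (otherwise 500 or
750 mg), and 1–7 post-dose samples per subject (mean ≈ 3) drawn without
replacement from a 0.5/1/2/4/6/8/12-h grid.

Continuous covariates follow lognormal distributions centered at the
stated medians with hard truncation at the stated ranges (log-scale SDs
0.25 / 0.18 / 0.45 for age / weight / creatinine, chosen once so the
untruncated distributions span the ranges with realistic right skew —
creatinine in particular is strongly right-skewed). Sample counts follow
a Poisson(3) truncated to 1–7 (truncated mean 3.09). CRCL is always
*computed* from the sampled covariates via Cockcroft–Gault, never sampled
independently, so its joint distribution with age/weight/sex is coherent.
`simulate_observations()` adds residual error, floors concentrations at
0, and flags (but retains) values below the 0.25 mg/l assay
quantification limit — no censored-data likelihood is used because
concentrations near that limit are vanishingly rare under this design.

What the generator does **not** emulate: real sampling-time patterns
(actual draw times cluster around nursing shifts, not a grid), dose
individualization already applied by clinicians (doses here are
independent of covariates), within-subject covariate drift (creatinine
changes during therapy), repeated dosing before sampling, and any
model misspecification. Passing recovery tests on these cohorts therefore
demonstrates the estimator is consistent *under the model*, not that the
model is right for any particular hospital's data.

## Problem sizes and runtime choices

The test suite runs every stochastic property at sizes chosen to balance
statistical power against runtime: 58-subject cohorts for parameter
recovery (20 replicate cohorts for the averaged check), 200 null
datasets of 30 subjects for the covariate-selection calibration, 200
bootstrap replicates, 300-replicate VPCs, and 1,000 virtual patients per
dosing stratum (matching the analysis size). The quadrature oracle runs
on 1–3-subject instances where dense 2-D integration is exact for
practical purposes.

## Known limitations

- Random effects are limited to independent $\eta$ on CL and V — no
  covariance, no inter-occasion variability.
- No SAEM/Bayesian estimation; FOCE-I linearization error, though bounded
  by the quadrature checks at the study's variability levels, grows with
  BSV.
- Steady-state dosing records (SS/II) are not parsed; steady state is
  handled analytically in the dosing module only.
- RSEs for variance components near their boundary are unreliable (the
  OFV is one-sided there); they are reported but flagged.
- The two-compartment path uses the slower R engine and shares the
  one-compartment BSV structure ($\eta$ on CL and V only).
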