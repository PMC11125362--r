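---
title: "Population PK simulation and estimation for zolpidem overdose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK simulation and estimation for zolpidem overdose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zolpitox)
```

## The clinical problem

Zolpidem is among the most frequently ingested drugs in intentional
overdose. A physician receiving an unconscious patient who reportedly
swallowed a known number of tablets cannot measure the plasma concentration
quickly, but a population pharmacokinetic model can predict its likely
trajectory: how high the concentration will go, and for how long it will
stay above the concentration thresholds associated with toxicity
(500 ng/mL), coma (1500 ng/mL), and fatality (4000 ng/mL); the
therapeutic window is 80–200 ng/mL. `zolpitox` packages the full loop
around that question: a structural PK model, its population (mixed-effects)
layer, Monte Carlo simulation with threshold-duration summaries,
non-compartmental analysis, and an FOCE-I estimation stack so the entire
model-building workflow — fit, likelihood-ratio testing, bootstrap,
visual predictive check — can be exercised on synthetic data.

## Structural model

A one-compartment model with first-order absorption, first-order
elimination, and an absorption lag. For a dose $D$ (mg) given at time 0,
with $\tau = t - t_{lag}$ and $k_e = CL/V$:

$$C(t) = 1000\,\frac{D\,k_a}{V\,(k_a - k_e)}
  \left(e^{-k_e \tau} - e^{-k_a \tau}\right), \qquad \tau > 0,$$

and $C(t) = 0$ at or before the lag. The factor 1000 converts mg/L to
ng/mL, the unit in which the clinical thresholds are quoted. Default
typical values are the final-model estimates: $K_a = 5.41$/h,
$V_d/F = 61.7$ L, $CL/F = 16.9$ L/h, $ALAG = 0.394$ h. Parameters are
apparent (scaled by the unknown oral bioavailability $F$), the natural
parameterization for oral data.

Numerical choices:

* When $|k_a - k_e| < 10^{-8}\,k_e$ the closed form suffers catastrophic
  cancellation; an explicit limit branch
  $1000\,(D/V)\,k_e\,\tau\,e^{-k_e\tau}$ takes over. Tests confirm
  continuity across the switch.
* Multiple doses superpose linearly; each event's lag clock starts at its
  own dose time. Superposition of the closed form — not stateful ODE
  integration — is the production evaluator, for exactness and Monte Carlo
  speed.
* An independent ODE oracle (`ode_oracle()`, depot/central system
  integrated with `deSolve::lsoda` at `rtol = 1e-10`) exists purely for
  cross-validation. Agreement is checked to $10^{-6}$ relative, with the
  comparison floored at $10^{-8}$ of the profile peak: below that the
  integrator's absolute tolerance, not the model, dominates the
  discrepancy.

## Population layer

Individual parameters are lognormal around the typical values,
$P_i = \theta\,e^{\eta_i}$, with $\eta \sim N(0, \Omega)$ on
$(K_a, V_d, CL)$ and no random effect on the lag. $\Omega$ couples
$V_d$ and $CL$ through a correlation $\rho_{V_d\text{-}CL} = 0.853$;
$K_a$ varies independently. Residual error is proportional:
$DV = IPRED\,(1 + \varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$.

Two reporting ambiguities had to be resolved, and both are surfaced as
options rather than buried:

* **CV% to $\omega^2$.** Interindividual variability is quoted as CV
  percentages (158.91, 22.10, 32.60 for $K_a$, $V_d$, $CL$). The default
  transform is the exact lognormal relation
  $\omega^2 = \ln(1 + CV^2)$, consistent with the stated lognormal model;
  `omega_from_cv(convention = "sd-equals-cv")` gives the common reporting
  shortcut $\omega^2 = CV^2$. The two differ negligibly for $V_d$ and
  $CL$ but materially at the 159% CV of $K_a$. Under the default, the
  simulated dose-escalation table reproduces the reference percentages
  (see below), which supports that reading.
* **"Proportional error 0.284".** Interpreted as the SD $\sigma$
  (28.4% CV), not the variance: $\sigma^2 = 0.284$ would imply >50% noise,
  inconsistent with the tight observed profiles.

Sampling uses a lower-triangular square root of $\Omega$ (eigendecomposition
fallback for singular-but-PSD inputs, e.g. $\rho = 1$), with a fixed draw
order — subjects outer, components inner — so a seed fully determines a
cohort. No truncation is applied to the $\eta$ draws.

## Monte Carlo simulation and threshold durations

`simulate_population()` samples a cohort and evaluates each subject's
closed-form curve on a grid that is dense (0.02 h) through the absorption
phase up to 4 h and sparser (0.25 h) out to 24 h — beyond nine typical
elimination half-lives, where the typical concentration is below 0.2% of
its peak. The grid contains the clinical sampling times as a subset.
Percentile bands (default 5th/50th/95th) use the linear-interpolation
quantile definition (`stats::quantile` type 7); the reference publication
does not state one, so it is fixed and documented here.

Residual (assay) error is **excluded** from threshold-duration analyses
and percentile plots by default: the simulator describes the smooth
individual-predicted curve of an unobserved patient, and the time a noisy
curve spends above a threshold is ill-defined. The VPC, which emulates
measured data, includes it.

`duration_in_band()` computes the total time the curve spends inside
$[lo, hi)$ by bracketed root-finding (tolerance $10^{-6}$ h) on the rising
and declining limbs of the single-dose curve; multi-dose regimens fall back
to sign-change scanning on a 0.005 h grid with root refinement. Durations
are binned as NR (exactly zero), <1, 1–2, 2–3, >3 h; ties at bin edges go
to the upper bin, a measure-zero choice at Monte Carlo scale.

`threshold_summary()` defaults to the *time-above-threshold* metric: each
severity row reports the time spent above that level's lower cut-point
(500, 1500, 4000 ng/mL), NR meaning the level was never reached. The
choice was settled empirically: both metrics produce rows summing to
100%, but only time-above-threshold reproduces the reference table's
toxic and comatose rows at high doses — at 1120 mg every simulated curve
blows through the 1500–4000 band in well under 3 h on its way up, so band
*occupancy* cannot yield the published "100% > 3 h" comatose row, while
time above 1500 ng/mL does. The occupancy metric remains available
(`metric = "within"`), and is what a band-specific exposure question
calls for.

## Non-compartmental analysis

`nca_params()` implements the standard definitions: $C_{max}$/$T_{max}$
read off the data; AUC by the linear-up/log-down rule (logarithmic
trapezoid on strictly declining segments with positive endpoints, linear
otherwise); $\lambda_z$ by log-linear regression over trailing subsets of
at least three post-peak points with $C_{max}$ excluded, choosing the
subset with maximal adjusted $R^2$ (near-ties within $10^{-4}$ resolve to
the larger subset) — the dominant convention in NCA software, stated here
because the reference names the quantity but not the selection rule. Then
$AUC_\infty = AUC_{last} + C_{last}/\lambda_z$, $t_{1/2} = \ln 2/\lambda_z$,
$CL/F = 1000\,D/AUC_\infty$, $V_d/F = (CL/F)/\lambda_z$.

## FOCE-I estimation

The estimation layer is the package's own implementation of first-order
conditional estimation with interaction. Per subject, the conditional mode
$\hat\eta_i$ minimizes

$$g(\eta) = \sum_j \left[\frac{(y_{ij} - f_{ij}(\eta))^2}{\sigma^2 f_{ij}(\eta)^2}
  + \ln \sigma^2 f_{ij}(\eta)^2\right] + \eta^\top \Omega^{-1} \eta,$$

found by a damped Gauss–Newton search (gradient tolerance $10^{-8}$,
model derivatives by central finite differences). The subject's
contribution to the objective is the linearized marginal form

$$OFV_i = \ln\det C_i + r_i^\top C_i^{-1} r_i,\qquad
  C_i = G_i \Omega G_i^\top + \mathrm{diag}(\sigma^2 f_i(\hat\eta)^2),\quad
  r_i = y_i - f_i(\hat\eta) + G_i\hat\eta,$$

with $G_i$ the model gradient in $\eta$ at the mode — residual variance at
the *conditional* prediction is the "interaction". The $n\ln 2\pi$
constant is omitted, so objective drops compare to the usual
$\chi^2$ cutoffs (3.84 for one added parameter at $\alpha = 0.05$, applied
strictly). CWRES are the Cholesky-decorrelated components of $r_i$,
approximately standard normal under a correct model. The inner problem is
compiled (Rcpp/RcppArmadillo) so that bootstrap-scale refitting stays
within minutes.

The outer search runs on an unconstrained scale — log typical values, a
log-Cholesky factor of $\Omega$ restricted to the $K_a$-independent /
$(V_d, CL)$-correlated structure actually reported, and $\log\sigma$ —
via `nlminb`. The inner search starts from a fixed point (zeros, or a
user-supplied warm start held constant), keeping the objective a
deterministic function of the outer parameters. Standard errors come from
the inverse numerical Hessian and are labelled as such; the Hessian uses
wide (0.01) finite-difference steps because the objective carries
$\sim 10^{-5}$ inner-solve noise that corrupts narrow-step curvature
estimates, while the surface is near-quadratic on the log scale at that
width. `nlminb`'s "false convergence" diagnostic fires routinely at
genuine optima of such an objective, so convergence is instead declared by
an explicit central-difference gradient check (max component < 0.1).

Zero concentrations (pre-dose samples, samples drawn before the absorption
lag, rare truncated draws) are incompatible with a proportional-error
likelihood — the variance collapses with the prediction — and carry
`mdv = 1`. Inside the likelihood, predictions are floored at
$10^{-6}$ ng/mL.

Verification strategy: with $\Omega = 0$ the objective must equal the
pooled proportional-error criterion in closed form; at small IIV the
linearization is near-exact and the per-subject objective is checked
against brute-force Monte Carlo integration of the marginal likelihood
(the model is never linear in $\eta$, so this replaces the textbook
linear-model identity as the exactness check); at $\sigma \to 0$ parameter
recovery is exact. At the study noise level ($\sigma = 0.284$) the
linearization leaves a few percent of bias on $V_d$/$CL$ and a downward
bias of order 15% on $K_a$ (whose 159% CV stresses the approximation
most); this is a property of FOCE-I itself, not of the implementation, and
bounds in the recovery tests are budgeted as approximation bias plus two
to three sampling standard errors at the test's cohort size.

## Synthetic study generator

`generate_study()` emulates the rich-sampling single-dose design behind
the model: 23 subjects (12 male, 11 female), one 10 mg oral dose, samples
pre-dose and at 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12 h, lognormal
IIV and proportional residual error at the reported magnitudes. Negative
error draws (rare at $\sigma = 0.284$) are truncated to zero and flagged,
concentrations being physically nonnegative. No sex effect is generated by
default (none was found in the reference analysis); `sex_cl_ratio` can
inject one for power studies. What the generator does *not* emulate:
digitization error of the source data, demographic covariates beyond sex,
BLQ censoring by an assay quantification limit, and dissolution-limited
absorption at massive tablet counts — so passing tests demonstrate
internal consistency of the method stack under the stated model, not
agreement with any particular patient population.

## Problem sizes and reproducibility

The shipped checks use cohort sizes chosen to keep Monte Carlo error well
inside the decision tolerances while running on a single core in minutes:
10,000 subjects per dose for the duration tables (three binomial standard
errors at the 500-subject granularity of the reference table are the
comparison tolerance), 50,000 draws for variability calibration, 100
subjects for parameter recovery, 10 replicates of the 23-subject design
for the lag likelihood-ratio test, 200 bootstrap replicates, and VPCs with
300–1000 simulated replicates. `scripts/acceptance.R` recomputes the
headline table cells from scratch at these sizes with a user-supplied
seed.

## Known limitations

* FOCE-I bias at high IIV and 28% proportional noise, as quantified above;
  a stochastic-integration estimator (SAEM) would reduce it but is out of
  scope.
* Single-ingestion focus: multi-dose superposition is implemented and
  tested, but threshold summaries target the overdose (single event) use
  case; no steady-state machinery.
* The bootstrap resamples subjects with replacement and refits; replicates
  that fail the gradient check are dropped and counted, which can bias CIs
  slightly narrow if failures cluster in extreme resamples.
* No covariate machinery beyond the single multiplicative sex factor on
  $CL$ or $V_d$ used for the reported covariate test.
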