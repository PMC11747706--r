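---
title: "Methods: population pharmacokinetics and initial-dose optimization of sertraline in pediatric MDD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and initial-dose optimization of sertraline in pediatric MDD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sertraline, an SSRI used in pediatric major depressive disorder (MDD), has
a reference therapeutic trough window of 10–150 ng/mL, wide between-patient
pharmacokinetic variability, and a clinically relevant drug–drug
interaction with the hypnotic zopiclone (both drugs compete for CYP3A4).
Therapeutic drug monitoring (TDM) can adjust maintenance doses after the
fact, but the *initial* dose must be chosen from a model. `sertmipd`
implements that model-informed precision dosing workflow end to end:
structural kinetics, population model, mixed-effects estimation with
stepwise covariate selection, bootstrap/VPC qualification, and Monte Carlo
dose optimization. Because clinical TDM databases are not redistributable,
the package also ships a synthetic-cohort generator that emulates the
demographic structure of a real pediatric TDM population (111 subjects,
body weight 56.58 ± 15.01 kg on 35–117 kg, 3/111 on zopiclone).

## Structural and population model

Concentrations follow a one-compartment model with first-order absorption.
Sparse pre-dose (trough) sampling cannot identify an absorption lag or
bioavailability F, so all parameters are apparent: clearance CL/F, volume
V/F, absorption rate Ka. Predictions are closed form; at steady state under
dose D every τ hours,

$$C_{ss}(t) = \frac{D\,k_a}{V(k_a-k_e)}\left[\frac{e^{-k_e t}}{1-e^{-k_e\tau}}
  - \frac{e^{-k_a t}}{1-e^{-k_a\tau}}\right],\qquad k_e = CL/V ,$$

with the analytic limit form used when $|k_a-k_e| < 10^{-6}\,\max(k_a,k_e)$
(the switch-over is far above double-precision cancellation at the time
scales involved; the ODE-oracle tests cover $k_a$ within $10^{-8}$ of
$k_e$). Units are mg, L, h internally; concentrations convert to ng/mL
(×1000) at the reporting boundary. Troughs are evaluated exactly at
$t=\tau$ post-dose at steady state — the standard TDM pre-dose convention —
and steady state is imposed analytically rather than by simulating a
titration run-in, which keeps simulated designs deterministic given the
random effects.

The population model (`sertraline_final_model()`) is

$$CL/F = 74\cdot(WT/70)^{0.75}\cdot(1-0.547\cdot ZOP)\ \text{L/h},\qquad
  V/F = 874\cdot WT/70\ \text{L},\qquad K_a = 0.5\ h^{-1},$$

with a single log-normal random effect on clearance,
$CL_i = CL_{typ}e^{\eta_i}$, $\eta_i\sim N(0,\omega^2)$, and combined
residual error $B = C(1+\varepsilon_1)+\varepsilon_2$. Covariate effects
use the field's two standard sub-models: power functions of continuous
covariates centered on the dataset median, and linear factors
$(1+\theta x)$ on binary covariates. Allometric exponents (0.75 on
clearance, 1 on volume) and Ka are fixed, not estimated: trough-only
designs carry essentially no absorption information, which the `ka_sweep()`
flatness tests demonstrate directly.

**Variability entries are standard deviations.** Reported variability
values (ω = 0.391, σ₁ = 0.159, σ₂ = 9.803 ng/mL) are ambiguous between
standard deviations and variances in the way such tables are commonly
printed. This package reads them as standard deviations (≈39% CV on
clearance, 15.9% proportional error, 9.8 ng/mL additive error): under that
reading the simulated attainment probabilities land within the published
Monte Carlo error of the printed ones, while the variance reading
(ω ≈ 0.63) misses them by ~20 percentage points. The `omega_mode` /
`sigma_mode` flags make the alternative convention available everywhere,
and every fit report and pipeline manifest records the mode in force.
Residual ε draws are Gaussian (the conventional choice for a symmetric
zero-mean error). Negative realized observations are kept as-is during
simulation for estimation — truncating them would silently change the
declared error model — and can be floored at zero in reporting layers via
the `truncate` flag.

## Synthetic cohorts

`generate_cohort()` draws body weight from a truncated log-normal whose
*truncated* mean and SD are moment-matched (closed-form truncated moments,
solved numerically) to 56.58 / 15.01 kg on [35, 117] kg; the log-normal
respects positivity and the right skew implied by a median (52.5) below
the mean. Zopiclone flags are Bernoulli at the study prevalence 3/111.
Maintenance doses are drawn uniformly over the clinical 0.5–5 mg/kg/day
range, once or twice daily with equal probability, exact in mg/kg by
default (tablet-strength rounding available). Each subject contributes 1–3
steady-state troughs on distinct visit days (the per-patient sampling
count of the real database is unpublished; 1–3 is the declared
assumption). The generator does **not** emulate adherence lapses, dose
titration, assay quantification limits, inter-occasion variability, or
covariate correlations (weight–age etc.), so passing tests demonstrate
estimator and simulation correctness under the declared data-generating
process, not robustness to those real-data features.

## Estimation

The objective function is −2 × the approximate marginal log-likelihood,
constants included, summed over subjects. With a single random effect the
marginal likelihood is a 1-D integral per subject; the package
approximates it by FOCE-with-interaction (default) or a full Laplace
approximation. Both first locate each subject's conditional mode — all
subjects simultaneously, by a damped Newton iteration on numerically
differentiated per-subject objectives (step clamp ±2, backtracking
halving, gradient tolerance 1e-7) — and differ only in the curvature term:
Gauss–Newton with residual variance at the individual prediction (FOCE-I)
versus the exact numerical second derivative (Laplace). Quadrature tests
verify both against brute-force integration (relative OFV error below
0.5% for Laplace and 2% for FOCE-I at ω = 0.391, shrinking by an order of
magnitude at small ω). A subject whose curvature at the mode
is not positive makes the OFV non-finite with the subject reported, never
silently patched.

The outer problem runs BFGS on transformed parameters — log for positive
parameters, log(1+θ) for linear covariate coefficients so the clearance
multiplier stays positive, identity for power coefficients — with a
Nelder–Mead fallback and up to two BFGS restarts from the best visited
point (a stale quasi-Newton Hessian otherwise stalls a few percent of
bootstrap refits). The best visited point is always returned. Standard
errors come from the numerically differentiated outer Hessian
(covariance 2H⁻¹ on the transformed scale, delta method back), reported
only when the Hessian is positive definite.

On sparse trough-only designs, typical clearance and volume are jointly
weakly identified (a likelihood ridge: higher V flattens the profile and
trades off against higher CL). The clearance estimator remains
approximately median-unbiased but diffuse — replicate SD ≈ 11 L/h at the
study design, matching the reported 12.1% SE — while volume recovery needs
richer, timed post-dose sampling, available through the cohort spec.
Stepwise covariate selection follows the OFV criteria: forward inclusion
at ΔOFV > 3.84 (p < 0.05, 1 df, greedy best-first; ties by larger drop
then candidate order), backward elimination at ΔOFV > 6.63 (p < 0.01),
candidates on clearance by default since the final model carries
covariates there. Under the null the implementation reproduces the χ²(1)
calibration: ~5% selection at 3.84 over 200 simulated datasets.

## Qualification

`bootstrap_ppk()` resamples *subjects* with replacement (respecting
within-subject correlation; the resampling unit is a declared choice),
refits warm-started from the point estimates, excludes and counts failed
or non-converged replicates, and flags results with >20% failures. Bias is
(median − estimate)/estimate × 100. `vpc_ppk()` quantities use 6 time-quantile
bins by default, type-7 percentiles, and re-simulate only the random
effects and residual errors on the original design; prediction correction
is out of scope. `gof_table()` reports PRED (η = 0), IPRED (empirical
Bayes η), iWRES standardized by the residual SD at the individual
prediction, and an analogous population-level weighted residual; empirical
Bayes shrinkage leaves the iWRES spread at or slightly below 1, which the
standardization test acknowledges explicitly.

## Dose optimization

`pta_grid()` simulates, per (weight, dose, interval, zopiclone) cell,
virtual patients from the final model and scores the fraction whose
steady-state trough lies inside [10, 150] ng/mL inclusive. Two declared
choices matter here:

* **Attainment metric: model-predicted trough, residual error off.** The
  window is a trough-referenced range and the trough is what TDM measures.
  Adding observed-scale measurement noise (`include_residual = TRUE`,
  available and tested) lowers every attainment probability by 3–4
  percentage points and moves the simulated minima outside the published
  Monte Carlo error of the printed probability ranges, so the
  noise-free-trough reading is the default.
* **Band statistic: mean across the band's grid weights** (ties to the
  lower dose for safety). The conservative worst-weight rule (`"min"`) is
  available; under this reconstruction the 3.0 vs 4.0 mg/kg/day attainment
  curves for once-daily dosing without zopiclone cross near 44 kg rather
  than exactly at the published 38.5 kg band edge, so the min rule can tip
  the 38.5–80 kg band to 4.0 on the 40-kg edge cell while the band mean
  reproduces the published recommendation table. Both statistics are
  reported with the attainment range across the band.

Weight-band endpoints (30–38.5, 38.5–80 kg) are taken as given; mg/kg
doses are exact. Per-cell seeds derive deterministically from the scenario
seed (`derive_seed()`), so grids are reproducible cell by cell. The dose
margins can be small — ~0.2 percentage points between 4.0 and 5.0
mg/kg/day at 30 kg — so recommendation runs should use enough virtual
patients per cell for the Monte Carlo SE to resolve the margin; the
acceptance checks use 10⁵–10⁶ where needed, while exploratory grids at the
published 1,000/cell are fine for plotting.

## Problem sizes used in the shipped checks

Deterministic analytic checks run instantly; stochastic checks are scaled
to stay informative at desk scale: 20 replicate 111-subject cohorts for
clearance recovery (8 enriched-prevalence replicates for the interaction
coefficient), one 200-replicate bootstrap, 200 scaled-down datasets (40
subjects) for the null-selection calibration, 15 datasets × 4 bins for VPC
self-consistency, and 3,000 virtual patients per attainment cell
(10⁵–10⁶ for the recommendation argmax, per the margin analysis above).

## Known limitations

* Exact objective-function values of the original study are not
  reproducible without its raw TDM data and exact estimator settings; the
  package targets the reported final-model parameters and the simulation
  claims that depend only on them.
* The clearance/volume ridge means single-fit volume estimates on
  trough-only data are unstable (as the published 36.6% SE and wide
  bootstrap interval already indicate); interpret them accordingly.
* One random effect (clearance) only: no inter-occasion variability, no
  IIV on volume or absorption, no random-effect covariance — matching the
  final model's scope.
* Bayesian individual dose adaptation from observed TDM feedback is out of
  scope; the package optimizes the initial dose only.
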