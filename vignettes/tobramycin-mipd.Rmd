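---
title: "Methods: Bayesian precision dosing of once-daily tobramycin in adult CF"
author: "tobramipd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian precision dosing of once-daily tobramycin in adult CF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model and the design decisions behind
`tobramipd`: what is computed, under which assumptions, which defaults
matter, and what the shipped synthetic experiments do and do not
demonstrate about real clinical data.

## The clinical problem

Adults with cystic fibrosis receive repeated 14-day courses of once-daily
IV tobramycin for *Pseudomonas aeruginosa* pulmonary exacerbations.
Efficacy is peak-driven (target peak/MIC of 8–10, operationalised as a
peak of 30–40 mg/L against the 4 mg/L susceptibility breakpoint) while
toxicity tracks sustained exposure, so the 24-h trough must stay below
0.5 mg/L. One TDM occasion per course — a peak drawn about 30 min after
the end of the infusion and a trough at 24 h — is the entire individual
information budget. The package turns those two samples plus covariates
into an individualised dose on the 25-mg grid that pharmacy can prepare.

## Structural and covariate model

Disposition is a linear two-compartment model with zero-order infusion
into the central compartment. With elimination `Ke` from the central
compartment and transfer constants `k12`, `k21` (all h⁻¹), the hybrid
constants are the roots of `λ² − (Ke+k12+k21)λ + Ke·k21 = 0`. The
response to a constant-rate infusion switched on at time 0 is, per litre
of central volume,

    S(t) = c_α (1 − e^{−αt})/α + c_β (1 − e^{−βt})/β,
    c_α = (α − k21)/(α − β),   c_β = (k21 − β)/(α − β),

and any dosing history is a superposition of `rate × [S(t−t₀) −
S(t−t₀−T_inf)]` terms. This "switch-on minus switch-off" form is exact,
continuous at the end of infusion, and remains well defined as `β → 0`
(the factor `(1−e^{−λt})/λ` is evaluated by its limit `t` for small
`λt`). The repeated root `α = β` can only occur when `k12 = 0` with
`Ke = k21` (the discriminant equals `(Ke−k21)² + k12² + 2k12(Ke+k21)`);
it is handled by the analytic limit, triggered at `|α−β|/α < 1e-9`.
The one-compartment case `k12 = k21 = 0` reduces exactly to
`R₀/(Ke·V1)(1−e^{−Ke·t})`. The test suite checks all of this against
independent numerical integration of the ODE system (`deSolve`) at
1e-6 relative accuracy.

Population parameters are linked to covariates by `V1 = Vs × BW` and
`Ke = KI + KS × CLcr`, with creatinine clearance from Cockcroft–Gault.
Serum creatinine is stored in µmol/L (the local laboratory convention)
and divided by 88.4 inside the formula; no upper cap is applied to the
result. Time is in hours, with each course's clock starting at its first
infusion; peripheral amounts start at zero (courses are weeks apart, so
carry-over is ignored).

## Discrete Bayesian estimation

The prior is nonparametric: support points `(Vs, KI, KS, k12, k21)` with
probability weights. Estimation is exact Bayes on that finite support:
`w_i ∝ prior_i × exp(logL_i)`, normalised via log-sum-exp. The
observation model is Gaussian with SD `= c0 + c1·C` evaluated at the
model prediction; the defaults `c0 = 0.1` mg/L (half the 0.2 mg/L LLOQ)
and `c1 = 0.04` (the assay's 4% repeatability bound) stand in for the
clinical assay's unpublished error polynomial and are configurable.
Likelihoods use the *recorded* infusion durations and sampling times,
never the nominal ones — that is the point of model-based TDM.
Below-LLOQ concentrations (strictly `< 0.2` mg/L; 0.2 itself is
quantifiable) are substituted at 0.1 mg/L before fitting. A censored
(M3-type) likelihood is deliberately not used: the substitution rule is
the deployed practice being modelled.

Reported quantities split by purpose:

* **Parameter point estimates** are posterior-weighted means of the
  population-scale parameters mapped through the covariate model
  (clearance `= Ke·V1`).
* **Individual predicted concentrations** come from the MAP (modal)
  support point. With a discrete grid prior, any weighted-average
  prediction retains a bias of the order of the grid spacing however
  informative the data (measured at ~1% and essentially independent of
  grid density between 200 and 5000 points), whereas the modal
  prediction collapses onto the generating point as noise vanishes —
  the behaviour a goodness-of-fit plot should have.
* **Dose design** uses full posterior expectations (below), not any
  single point.

Goodness of fit is summarised by the prediction error `PE = predicted −
observed` (median and IQR; the sign convention makes underprediction
negative and is stated here because it is easy to get backwards), the
absolute percentage error, and the R² of the observed-versus-predicted
regression (0 by convention for constant predictions).

### Hybrid fit

Some patients genuinely lie outside the prior's support. The fit is
declared inadequate when more than 50% of posterior mass sits within the
outer 5% (log scale) of a *single bound of a single dimension*, or when
the median APE exceeds 20%. The one-sided, per-dimension definition
matters: a symmetric linear-scale "near any edge" rule would label ~40%
of a log-uniform grid's mass as boundary and fire on nearly every
course. On trigger, every dimension's range is widened by a factor of 2
on the log scale about its midpoint, a 500-point quasi-random (Halton)
auxiliary grid carrying half the prior mass is appended, and the
posterior is recomputed. The expansion factors are conservative defaults
chosen to be testable, not a reconstruction of any proprietary scheme.

## Dose design

For support point `i`, the standardised peak is linear in dose:
`Cmax_mod = a_i · D`, with `a_i` the per-mg concentration 1.0 h after
the start of the last of seven once-daily standardised 0.5-h infusions
(explicit 7-dose superposition ≥ 99% of the asymptote for the slowest
plausible terminal slope, and free of repeated-eigenvalue corner cases
that closed-form accumulation would add). The continuous dose minimises
the posterior-expected squared deviation from target `T`:

    D* = T · Σ w_i a_i / Σ w_i a_i².

`D*` deliberately shades below the naive `T/E[a]` when the posterior is
wide — that is the squared-error optimum — so its expected peak is
`T·E[a]²/E[a²] ≤ T`. Rounding therefore goes *up* the 25-mg grid to the
first multiple at which the expected peak attains the target: the grid
dose is `ceil(max(D*, T/E[a]))` on the grid. This is at most one step
above the plain ceiling of `D*`, is identical to it for a single-point
posterior, and reflects the clinical reading of "rounded to the next
25 mg" in a service whose failure mode was under-dosing. The report
carries all three rungs (30/35/40 mg/L) with predicted peak and 24-h
trough; a predicted trough at or above 0.5 mg/L or a rounded peak
outside 30–40 mg/L appends a warning. The once-daily interval is never
changed — interval extension for renal impairment is out of scope — so
the trough flag is informational. An alternative design that doses the
posterior-mean-parameter patient is available
(`optimal_dose(method = "mean_parameter")`), and rounding to the nearest
grid multiple instead of up (`round_dose(mode = "nearest")`), but the
expectation-based objective with upward rounding is the default.

## Paired tests and cohort analytics

Dose changes (initial versus physician-accepted) and creatinine changes
(baseline versus end of therapy) are compared with the two-sided
Wilcoxon signed-rank test: zero differences dropped, exact null for up
to 25 tieless differences, normal approximation with tie and continuity
corrections otherwise (the implementation wraps `stats::wilcox.test`;
the test suite verifies it against exhaustive sign-pattern enumeration
for all patterns up to n = 10). The AKI marker is a ≥ 50% rise in serum
creatinine — inclusive, reconciling "an increase of 50%" with "greater
than 50%" in the source material — with missing end-of-therapy values
counted as unevaluable, never imputed. Peak bins use the closed interval
[30, 40]; the trough criterion is strict (`< 0.5`). Cohort proportions
are recomputed from the per-course classification lists, never tallied
independently.

## The synthetic cohort

No patient data ship with the package; the generator emulates the study
conditions so every stage is testable end to end. Per course:

* weight ~ N(57.5, 12.3²) kg truncated to [35, 80] (bounds symmetric at
  ±1.8 SD so the truncated mean stays on target); age ~ N(32.4, 10²)
  truncated [18, 65]; sex Bernoulli(53/77); CLcr ~ N(112.7, 28.4²)
  truncated [30, 200], with serum creatinine back-solved through the
  Cockcroft–Gault inverse so the derived clearance equals the draw;
* initial dose ~ N(9.16, 1.42²) mg/kg × weight, rounded to the *nearest*
  25 mg (ceiling rounding would bias the mean by ~+0.22 mg/kg and break
  the mg/kg calibration; ceiling is reserved for recommendations, where
  it is the clinical rule);
* once-daily dosing for 14 days; one TDM occasion on day 3 or 4 with
  infusion duration ~ N(35.9, 7.4²) min truncated [20, 60], a peak
  sample at N(32.1, 8.9²) min after the end of infusion truncated to the
  observed extremes [4, 69], and a trough 24 h after that infusion's
  start;
* multiplicative N(0, 0.04²) observation noise, floored at zero, with
  values below 0.2 mg/L flagged for BLQ substitution downstream;
* end-of-therapy creatinine: with probability 1/77 an AKI-range rise
  (ratio uniform on [1.5, 2]); otherwise a log-normal ratio with median
  1 and log-SD 0.15, calibrated against the generator so the cohort's
  CLcr start-to-end difference has SD ≈ 17.8 mL/min; 8/77 of end values
  are missing;
* true parameters are drawn from the analysis prior (so recovery tests
  have exact ground truth on the support); 17 of 61 patients receive a
  second course reusing their kinetics (PK is a patient property) with a
  freshly drawn baseline creatinine, giving exactly 78 courses.

All draws come from one RNG stream seeded once in `generate_cohort()`,
so cohorts are bit-for-bit reproducible.

When no prior file is supplied, the analysis prior is the built-in
synthetic default: 2000 Halton points, log-uniform over Vs ∈
[0.15, 0.55] L/kg, KI ∈ [0.003, 0.03] h⁻¹, KS ∈ [0.0015, 0.005] h⁻¹ per
mL/min, k12, k21 ∈ [0.05, 4] h⁻¹, equal weights. It is labelled
synthetic in code and output: it is *not* a published population model,
and its deliberately wide distribution ranges give the simulated
population heavier distribution-phase tails (hence higher 24-h troughs)
than real tobramycin cohorts exhibit.

### The under-target experiment

The shipped end-to-end experiment (`scripts/acceptance.R`, and the
corresponding acceptance test) reproduces the regime the dosing service
corrects: a "mismatch mode" scales every true `Vs` by
`vs_mismatch_default()` = 1.1 relative to the analysis prior.
Calibrated against the generator, this puts the estimated standardised
peak below 30 mg/L for well over 60% of courses at 9.16 mg/kg dosing
(the vague synthetic prior population is already under-dosed at that
level; the factor adds robustness across seeds). Applying the 30 mg/L
grid recommendation as the accepted dose then lifts expected in-range
attainment above 80%, raises doses significantly on the paired
signed-rank test, and — because the creatinine generator is independent
of dose by construction — leaves renal function unchanged.

### Problem sizes

The simulation studies use the sizes at which the method operates
clinically: 78-course cohorts for the end-to-end experiment, 100 courses
for the two-sample predictive check, 50 replicates of the 8-sample rich
design for parameter recovery, and 100 random parameter sets × 20 time
points for the kinetics oracle.

## What the synthetic experiments do not show

Truth drawn from the analysis prior is the well-specified regime; real
patients are not grid points, and real assay errors are not exactly the
affine Gaussian model. Passing recovery tests therefore demonstrates the
correctness of the estimator and dose logic, not the adequacy of the
synthetic default prior for clinical use — a deployment must supply a
validated population model as the prior file. Physician acceptance
behaviour, interval extension for renal impairment, MIC-individualised
targets, AUC-based targets and clinical endpoints are out of scope.

## Numerical conventions

* Weights renormalised to sum to 1 within 1e-12; log-sum-exp throughout.
* Boundary-mass tolerance 5% of the log-range, one bound at a time.
* Repeated-root switch at `|α−β|/α < 1e-9`; `(1−e^{−λt})/λ` by series
  limit below `|λt| < 1e-12`.
* Grid rounding uses a 1e-9 slack so exact multiples are not pushed up.
* Ties in the MAP point (identical maximal weights) resolve to the first
  index — deterministic given the prior file's point order.
* Concentrations are clamped at zero after superposition to absorb
  floating-point negatives of order 1e-16.
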