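---
title: "Biological-age clocks and mortality modelling in HFpEF: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological-age clocks and mortality modelling in HFpEF: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bioagehf` estimates biological age (BA) from routine clinical
biomarkers, derives BA *acceleration* — how much biologically older or
younger a person is than their chronological age (CA) predicts — and
models its consequences for mortality and left-ventricular (LV) structure
and function in cohorts with heart failure with preserved ejection
fraction (HFpEF). This vignette is the package's own account of the
models, the synthetic study conditions it is validated under, and the
numerical and design choices that were genuinely open.

## The two clocks

### Klemera–Doubal age

The Klemera–Doubal estimator treats each biomarker as a noisy linear
readout of an underlying biological age. In a reference cohort, each
(possibly log-transformed) biomarker is regressed on CA, giving slope
$k_j$, intercept $q_j$ and root-mean-squared error $s_j$. A new record
with biomarkers $x_j$ scores

$$\mathrm{KDMAge}
  =\frac{\sum_j (x_j-q_j)\,k_j/s_j^2 + \mathrm{CA}/s_{BA}^2}
        {\sum_j (k_j/s_j)^2 + 1/s_{BA}^2}.$$

Two conventions circulate for the denominator's biomarker term:
$\sum_j(k_j/s_j)^2$ and $\sum_j k_j/s_j^2$. Only the squared-ratio form is
dimensionally a precision (1/years²) and has the fixed-point property that
a biomarker profile exactly at its age expectation returns
$\mathrm{KDMAge}=\mathrm{CA}$; it is the package default
(`convention = "squared_ratio"`), with `"as_printed"` available for
audits of the alternative reading. Similarly, the quotient only has the
fixed point when $k$ is the *slope* and $q$ the *intercept* of the
biomarker-on-age regression; that orientation is used throughout.

$s_{BA}$ (years) controls how strongly CA anchors the estimate. The
default (`s_ba = "corrected"`) is the SD of (first-stage biomarker-only
age estimate − CA), corrected downward by the estimator's own
characteristic noise variance $1/\sum_j(k_j/s_j)^2$ — i.e. an estimate of
the true dispersion of biological age around CA. An `"explained"` mode
(SD of CA explained by the biomarker set) and a fixed numeric override
are provided because the verbal definitions in the literature differ.

### Phenotypic age

PhenoAge asks a different question: what CA would, in a reference
mortality model, carry the same 10-year death risk as this person's
biomarkers predict? Training fits a Gompertz proportional-hazards model
of all-cause mortality on CA plus the panel by right-censored maximum
likelihood (`flexsurv`), giving a linear predictor $xb$ and shape
$\gamma$ (per month). The 120-month mortality score is the Gompertz CDF

$$M = 1-\exp\!\big(-e^{xb}\,(e^{120\gamma}-1)/\gamma\big),$$

mapped to years with calibration constants $(c_0, c_1, c_2) =
(141.50225,\ 0.00553,\ 0.09165)$:

$$\mathrm{PhenoAge} = c_0 + \ln(-c_1 \ln(1-M))/c_2 .$$

A literal reading of the widely reprinted formula places the inner
logarithm as $\ln(-c_1)$, which is undefined; the parenthesization above
is the unique finite, monotone reading and inverts exactly
(`score_from_phenoage()` round-trips to 10⁻⁹ across $M\in(0.001,0.999)$).
When $-c_1\ln(1-M)=1$ the inner log vanishes and PhenoAge equals $c_0$;
because that $M$ is closer to 1 than double precision can represent,
`phenoage_from_score()` accepts `log1m_score` = $\ln(1-M)$ directly.
Setting `rederive_constants = TRUE` replaces the published constants with
ones derived from a univariate age-only Gompertz fit on the same
reference sample ($c_2=b_1$, $c_1=\gamma_u/(e^{120\gamma_u}-1)$,
$c_0=-b_0/b_1$), making PhenoAge exactly "the CA with equal reference
risk". Elastic-net penalization of the training fit is not implemented:
at a ten-biomarker panel and the sample sizes used here, plain maximum
likelihood is stable and penalty tuning would add a data-dependent layer
the validation suite would then have to marginalize over.

### Acceleration

Acceleration is the residual of BA on CA within the *analysis* cohort
(not the reference cohort), so it is orthogonal to CA by construction;
z-scores are standardized within the same sample, matching per-1-SD
reporting, and tertiles use sample cut-points with ties assigned to the
lower tertile (deterministic).

## Echocardiographic indices and eligibility

LV mass uses the standard Devereux formula
$0.8\cdot1.04[(\mathrm{IVS}+\mathrm{LVID}+\mathrm{PWT})^3-\mathrm{LVID}^3]+0.6$
(cm → g), indexed to Du Bois body surface area
$0.007184\,W^{0.425}H^{0.725}$; RWT is $2\,\mathrm{PWT}/\mathrm{LVID}$;
E/e′ divides mitral E by the mean of septal and lateral e′. Eligibility
requires LVEF ≥ 50% plus at least one of: sex-specific LVMI (> 115 g/m²
male, > 95 g/m² female), RWT > 0.42, E/e′ > 9, or rhythm-specific
NT-proBNP (> 125 pg/mL sinus, > 365 pg/mL in AF). All thresholds are
strict except the LVEF bound, exactly as printed in the criteria the
package mirrors. The H2FPEF score sums AF (3), BMI > 30 (2), and one
point each for age > 60, ≥ 2 antihypertensives, E/e′ > 9 and
PASP > 35 mmHg.

## Survival and regression machinery

Cox models use Efron tie handling (accurate for the moderate ties that
monthly follow-up produces). Adjustment tiers are nested: tier 1 = sex +
age; tier 2 adds drinking, smoking, hypertension, coronary artery
disease, diabetes, AF, stroke; tier 3 adds lipid-lowering,
antihypertensive, oral hypoglycemic and insulin use; tier "3n" adds log
NT-proBNP as a sensitivity adjustment. The complete-case set is fixed
over the *largest* tier's covariates before any tier is fitted, so `n`
and events are identical across tiers — the estimates differ by
adjustment, never by sample. Analyses are complete-case throughout; no
imputation is attempted.

Trend tests enter the ordinal tertile index (1, 2, 3) as a continuous
term. Restricted cubic splines use the 3-knot truncated-power basis with
knots at the exposure's 10th/50th/90th percentiles; the curve is
referenced to the exposure median (HR = 1 there by construction) and the
Wald test of the single nonlinear coefficient is the nonlinearity test.
The basis is written in the package (a dozen lines) rather than imported,
and its defining property — linearity beyond the boundary knots — is
asserted in the test suite. Subgroup analyses dichotomize age at 70 years
and BMI at 24 kg/m²; a stratifier that is itself an adjustment covariate
is dropped from its own stratified model, and the interaction p comes
from the exposure × stratifier product term in the pooled model.

## Mediation

The mediation estimator is regression-based with exposure–mediator
interaction: a linear model $M=\beta_0+\beta_1 A+\beta_2'C+\varepsilon$,
$\varepsilon\sim N(0,\sigma^2)$, and a Cox model with hazard multiplier
$\exp(\theta_1 A+\theta_2 M+\theta_3 AM+\theta_4'C)$, both fitted on one
complete-case set. Under the rare-outcome approximation the natural
effects on the log-HR scale for contrast $(a,a^*)$ are

$$\mathrm{NDE} = \big[\theta_1+\theta_3(\beta_0+\beta_1 a^*+\beta_2'c
   +\theta_2\sigma^2)\big](a-a^*)
   +\tfrac12\theta_3^2\sigma^2(a^2-a^{*2}),$$
$$\mathrm{NIE} = (\theta_2\beta_1+\theta_3\beta_1 a)(a-a^*),$$

with total = NDE + NIE exactly on the log scale. The default contrast is
(+1, 0) SD of acceleration and covariates are conditioned at sample
means. The proportion mediated is NIE/(NDE+NIE) on the log-HR scale by
default; the excess-HR alternative
$\mathrm{HR}_{NDE}(\mathrm{HR}_{NIE}-1)/(\mathrm{HR}_{NDE}\mathrm{HR}_{NIE}-1)$
is available because the verbal definition is scale-ambiguous. When the
total effect is numerically zero the proportion is reported as `NA` with
a warning rather than an unstable ratio. Confidence intervals come from a
participant-level nonparametric bootstrap (1000 replicates by default,
200 in the pipeline; percentile intervals; deterministic under a seed;
an error is raised if more than 10% of refits fail).

The closed form is never trusted on its own authority: the package also
ships `mc_natural_effects()`, a Monte-Carlo g-formula oracle that draws
mediator values under each exposure level and averages hazard multipliers
directly. Closed form and oracle agree to well below 0.01 log-HR at 10⁶
draws, and the estimator is additionally checked against
`true_natural_effects()` evaluated at the generator's configured truth.

Two caveats are inherent. First, the rare-outcome Cox formulation is an
approximation at a ~19% cumulative event fraction; the residual bias is
small for the proportion (a ratio in which it largely cancels) and is
quantified in the test suite. Second, when the exposure is the
*estimated* acceleration rather than the latent truth, measurement error
inflates the apparent mediated proportion (the mediator carries extra
information about the latent exposure); the validation suite therefore
tests recovery on the true latent exposure, and the pipeline's
estimated-exposure proportions should be read as the quantity an applied
analysis would actually report.

## The synthetic study conditions

`sim_config()` freezes the conditions the package is validated under.

* **Reference cohort** (n = 5000, ages uniform 30–75): latent
  acceleration $\delta\sim N(0,\tau^2)$ with $\tau$ = 10 years; each
  biomarker is linear in latent age $CA+\delta$ with Gaussian noise
  (blood urea nitrogen on the log scale, so its raw column is
  right-skewed and the log-transform rule has something real to detect).
  Mortality is Gompertz with shape 0.0075/month (hazard doubling ≈ 7.7
  years) and its log-rate is the precision-weighted biomarker combination
  whose expectation is $12\gamma\times$ latent age — i.e. the measured
  physiological state, not the unobservable latent variable, drives risk.
  This makes the Gompertz proportional-hazards fit correctly specified;
  putting the unobservable noise itself in the hazard would act as
  frailty and attenuate every shape estimate, so no finite sample could
  recover the configured $\gamma$. Follow-up is 15–30 years with uniform
  entry (administrative censoring), giving ~45% mortality — the scale of
  a long-linkage national reference sample.
* **Biomarker noise** is set to roughly 7 "age-years equivalent" per
  marker, so the ten-marker panel jointly measures latent age to about
  ±2.2 years. This is optimistic relative to real clinical panels
  (where single-marker noise is an order of magnitude larger); it is
  chosen so that parameter-recovery checks (slopes to 5%, shape to 10%)
  are statistically identifiable at n = 5000. Consequently the passing
  tests certify *estimator correctness*, not that real panels would
  achieve these precisions — with realistic noise the same estimators
  are unbiased but their sampling error dominates such bounds.
* **HFpEF cohort** (n = 1727, age ~ N(68.2, 10.6²) truncated to 40–95):
  LVMI is the primary mediator, $108 + 0.5\,\delta + N(0,20^2)$ g/m²;
  E/e′ a secondary one ($11 + 0.12\,\delta + N(0,3.5^2)$). Survival is
  Cox–Weibull (baseline $2.3\times10^{-3}\,t^{1.1}$, t in months) with
  per-SD log-HR $\theta_A = 0.4$ and mediator effect
  $\theta_M = 0.00421$ per g/m², chosen so the closed-form proportion
  mediated is exactly 5% — the magnitude reported for echocardiographic
  mediators in this literature. Censoring is uniform over 36–84 months,
  and cardiovascular deaths are an independent 56% thinning of all
  deaths, yielding the ~19%/~10% event design shape. Covariate and
  medication flags carry HFpEF-typical prevalences but are independent of
  $\delta$ — adjustment tiers are exercised without injecting
  confounding whose recovery would then need its own truth bookkeeping.
* **Eligibility by construction**: LVEF is truncated at ≥ 50% and RWT
  drawn above 0.43 (a concentric-remodelling phenotype), so every record
  passes the screen via a criterion *other than the mediator*. Rejection
  sampling on LVMI or E/e′ was deliberately avoided: conditioning
  eligibility on the mediator would select on it and silently distort
  the configured mediation truth.

What the generator does **not** emulate: the marginal biomarker
distributions of any real HFpEF cohort, competing risks (the two
endpoints are fitted separately, as in the analyses it mirrors),
longitudinal biomarker trajectories, confounding between covariates and
acceleration, and calibration offsets between reference and analysis
cohorts (real transported clocks often show a systematic
acceleration-mean shift; residualization absorbs it, so it is not
modelled).

## Numerical choices and degenerate inputs

Survival times are sampled by exact inverse transform (Gompertz:
$T=\ln(1-\gamma\ln U/\lambda)/\gamma$; Weibull:
$T=(-\ln U/(\lambda e^{lp}))^{1/\kappa}$) — no ODE or discretization.
Mortality scores at the double-precision boundary are clamped into the
open unit interval with a warning before the log transform. Strictly
positive analytes are floored at 0.01 in the generator. Tertile ties go
to the lower tertile; duplicated spline knots, constant biomarkers,
constant CA, all-censored training data, empty strata, collinear
covariates and missing scored biomarkers all raise typed errors naming
the offending column or record. All randomness flows from integer seeds;
generators and the bootstrap are bit-reproducible.

## Problem sizes in the validation suite

The suite runs at the sizes the checks need, scaled to finish in a few
minutes: reference recovery at n = 5000; Cox calibration with 200
replicates at n = 1500 (true per-SD log-HR 0.4; mean bias ≤ 0.02,
coverage within [0.92, 0.98]); spline type-I error over 400 replicates at
n = 800; mediation recovery over 100 replicates at n = 1727 and null
coverage over 40 bootstrap runs at n = 800; log-rank uniformity over 500
replicates at n = 240; consistency batches for OLS slopes (100 × n =
2000) and Gompertz shape (12 × n = 1500); and the full pipeline twice at
n = 1727 to confirm bit-identical outputs.

## Limitations

The package validates estimators against a generator whose structural
assumptions (linear biomarker drift, normal mediator, proportional
hazards, rare-outcome mediation algebra) match the estimators' own; it
cannot detect misspecification that real data would exhibit. The
published PhenoAge calibration constants are used verbatim by default, so
absolute PhenoAge levels in synthetic cohorts are interpretable only
relative to each other (acceleration, the quantity analysed, is
invariant to this). Competing-risks structure, multiply-robust mediation
estimators, multiple simultaneous mediators and time-varying exposures
are out of scope.
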