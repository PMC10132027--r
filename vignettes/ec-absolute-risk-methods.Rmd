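---
title: "Methods: ten-year absolute risk models for esophageal cancer"
author: "ecrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ten-year absolute risk models for esophageal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Esophageal cancer (EC) in China — overwhelmingly squamous cell carcinoma —
shows extreme geographic variation: a handful of high-risk areas have
incidence more than six times that of the rest of the country. Endoscopic
screening of everyone is infeasible, so the practical question is risk
stratification: given what a primary-care system already knows about a
person, what is their probability of developing EC in the next ten years,
accounting for the competing possibility of dying first?

`ecrisk` implements the full modelling workflow for this question:
cause-specific flexible parametric hazard models, competing-risk absolute
risk, recalibration for transport to a new population, a validation battery,
and a synthetic cohort generator that reproduces the structure of the two
cohorts this model family was built on — a nationwide development cohort of
roughly half a million adults aged 30–79 (23.2% living in high-risk areas,
median follow-up about 11.1 years) and a single low-risk rural external
validation cohort (median follow-up about 13.6 years). No individual-level
data from either cohort are available, so the generator is the package's
test bed: it makes every downstream stage executable and checkable.

## The hazard model

Both cause-specific models (EC incidence; all-cause mortality) are flexible
parametric models on the log cumulative hazard scale with **age as the
timescale** and delayed entry:

$$\log H(t \mid x) \;=\; \gamma_0 + \sum_{j} \gamma_j B_j(u(t)) + x^\top\beta,$$

where $u(t)$ is log age by default, and $B$ is a restricted cubic spline
with boundary knots at 30 and 90 years and internal knots at 60 and 70
years (four knots, hence three basis terms). The spline is the
Durrleman–Simon restricted truncated-power construction: term 1 is the
identity on the evaluation scale and the nonlinear terms are continuous with
continuous first and second derivatives and exactly linear outside the
boundary knots. We deliberately do not orthogonalise or centre the stored
basis (some implementations do by default): raw coefficients keep the knot
interpretation, and every quantity we validate — covariate hazard ratios,
cumulative hazards, absolute risks — is invariant to that choice. A
consequence is that printed spline-term coefficients are not comparable
between implementations, and we never treat them as estimands.

Whether the spline should be evaluated on age or log age is genuinely
ambiguous in this model family's practice; the package supports both
(`knot_spec(scale =)`), defaults to log age (the conventional choice, with
knots in years mapped through the log), and the test suite exercises both
scales.

The likelihood is the standard delayed-entry, right-censored form: a
participant entering at age $a_i$, leaving at age $t_i$, with cause
indicator $d_i$ contributes
$d_i \log h(t_i|x_i) - [H(t_i|x_i) - H(a_i|x_i)]$, with the competing cause
treated as censoring (cause-specific hazards). The hazard follows by the
chain rule, $h = H \cdot \mathrm{d}\eta/\mathrm{d}t$.

### Numerical choices

* **Optimisation.** BFGS with the analytic gradient, started from a
  deterministic exponential/Weibull initialisation, followed by damped
  Newton polish using the **exact analytic Hessian**; a Nelder–Mead restart
  guards against optimiser failure. The spline basis is standardised
  (centred, unit variance) internally during optimisation — the raw
  truncated-power columns differ by orders of magnitude and make the
  Hessian needlessly ill-conditioned — and coefficients are mapped back
  afterwards.
* **Convergence.** Declared when the optimiser's relative log-likelihood
  change falls below 1e-9 and the Newton decrement (the locally expected
  remaining log-likelihood improvement, an affine-invariant criterion) is
  below 2e-3. The decrement tolerance matters: data that carry no age-shape
  information at all (e.g. a constant hazard over a narrow age window) put
  the likelihood supremum on a flat ridge that no finite iterate attains,
  while any age-informative cohort converges many orders of magnitude below
  the tolerance. A raw gradient-norm criterion is not usable here because a
  few events with near-zero fitted hazard slope create curvature of order
  $10^6$, putting the gradient zero below double-precision resolution of
  the summed likelihood.
* **Monotonicity.** $H$ must be nondecreasing. This is checked after
  fitting on a 0.1-year grid over the boundary-knot range rather than
  imposed during optimisation (the common practice in this family);
  violations flag the fit with a warning. In the absolute-risk integrand,
  mild non-monotonicity in the sparse right tail of a fitted model is
  floored at hazard zero; gross violations are an error.
* **Variance.** Inverse observed information from the analytic Hessian;
  hazard-ratio intervals are Wald, $\exp(\beta \pm 1.96\,\mathrm{se})$.

### Model tiers

Four nested EC models are fitted: age-only; **simple** (+ sex, regional
risk level, education, family history of cancer — the predictors available
for all residents in basic public-health electronic records);
**intermediate** (+ smoking, alcohol use, BMI — additionally recorded for
residents aged 65+ and diabetic or hypertensive patients); **full**
(+ physical activity, tea temperature preference, fresh fruit consumption,
which go beyond routine records). Predictor selection is out of scope: the
tiers are taken as given. The mortality model uses sex, residence area and
regional risk level, and reuses the EC knot layout (the original layout for
the mortality model is not documented; this is recorded as an assumption).
No interactions are included.

## Absolute risk

The ten-year absolute risk at age $a$ is the cause-specific competing-risk
integral

$$AR(a) = \int_a^{a+10} h_{EC}(t|x)\,
  \exp\!\big(-[H_{EC}(t|x) - H_{EC}(a|x)] - [H_D(t|x_D) - H_D(a|x_D)]\big)\,dt,$$

the probability of an EC diagnosis before both the horizon and death,
conditional on being alive and EC-free at $a$. Conditioning at $a$ (left
truncation at prediction time) keeps risk accrued before the prediction age
out of the integral. The integrand is smooth, so composite Simpson
quadrature on a 0.1-year grid is used; halving the step changes results by
far less than 1e-8, and the suite checks agreement with an independent
adaptive integrator and with the two-cause constant-hazard closed form
$\lambda_1/(\lambda_1+\lambda_2)\,(1-e^{-(\lambda_1+\lambda_2)h})$.

## Recalibration

Models transported to a population with different background incidence
miscalibrate in level. The two-parameter recalibration used here follows
the WHO CVD Risk Chart working group's approach in spirit: across age
groups $g$ (5-year bands of entry age by default),

$$\log(-\log(1 - O_g)) = \log k + b\,\log(-\log(1 - P_g)),$$

estimated by least squares, giving a scale $k$ on the cumulative-hazard
scale and a slope $b$ on the cloglog scale; predicted risks are then updated
as $r' = 1 - \exp(-k\,[-\log(1-r)]^b)$. Two choices deserve note. First,
the exact published variant of the method (its "slight modification") is
not documented in accessible form; the cloglog-linear two-parameter form is
a reconstruction with exactly the two named parameters, both of which
exceed 1 when observed risks exceed predicted ones — the direction reported
for the external cohort. The published pair (b = 1.22, k = 1.97) is
therefore **not** a comparison target; the package's tests target
self-consistency (exact recovery of constructed transforms, round trips to
1e-10, rank preservation, hence invariance of the AUC). Second, the
regression is weighted by the event count per age group: the sampling
variance of the cloglog-transformed Kaplan–Meier risk scales inversely with
events, and unweighted least squares lets near-empty young age bands
dominate the fit at realistic cohort sizes.

## Validation battery

* **Eligibility.** Discrimination at the 10-year horizon uses only
  participants whose horizon status is settled: EC within 10 years (case),
  death EC-free within 10 years (non-case — the competing event settles the
  outcome), or EC-free follow-up past the horizon (non-case). Participants
  censored alive before the horizon are excluded from discrimination but
  retained for calibration. Counting deaths as non-cases rather than
  excluding them is the one place the eligibility rule required a decision;
  we follow the competing-risk logic (their ten-year EC status is known).
* **AUC** is the Mann–Whitney probability with ties counted ½, with DeLong
  placement-value intervals (checked against an independent implementation).
* **Calibration** is Kaplan–Meier observed 10-year risk (competing deaths
  censored, all rows included regardless of follow-up length) against mean
  predicted risk by decile of predicted risk, with Greenwood log-log
  intervals. Decile ties go to the lower decile.
* **Added value** between adjacent tiers: continuous NRI (ties contribute
  zero) and IDI, with 500-replicate bootstrap percentile intervals
  available.
* **Internal validation**: a 2/3–1/3 simple random split by participant
  (no stratification — none is documented for the original design), plus
  Harrell-style bootstrap optimism correction of the AUC (fit on the
  resample, evaluate on resample and original; 500 replicates by default).
  Subgroup discrimination is reported for region risk level, residence,
  sex, age group, and the "special population" of the basic public-health
  service (age 65+ or diabetes/hypertension), which the generator supplies
  as a flag because the cohort schema carries no diabetes/hypertension
  fields.
* **External validation** scores only the tiers whose covariates the
  external cohort measures (the full tier is skipped there, with the
  reason), reports discrimination and calibration before recalibration,
  estimates $(b, k)$, and re-reports calibration after; the AUC is asserted
  bit-identical before and after, since the recalibration map is strictly
  increasing.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are not tuning
knobs. What it reproduces:

* **Covariate structure.** Region stratum is sampled first (23.2%
  high-risk for the development profile; the external profile is entirely
  low-risk and rural). Age is truncated normal (mean 52.0, SD 10.7 years;
  51.2/12.1 for the external profile) on 30–79. Each categorical covariate
  is sampled by a rank-copula: categories are cut from the rank-uniform
  transform of a noisy age/sex score, so the configured marginal
  probabilities (taken from the published baseline tables) hold essentially
  exactly while the qualitative dependence seen in the source cohorts —
  smokers and drinkers overwhelmingly male, less education and less fruit
  at older ages — is present. We chose the copula over a raw logistic link
  because it preserves marginals by construction; a logistic dependence
  would need its intercepts recalibrated against every weight change.
  Published tables give only marginals, so any joint structure is a
  modelling choice; it is recorded in the config object.
* **Event-time truth.** EC ages are drawn by inverse transform from
  $H(t) = \exp(\gamma_0^{(s)} + \gamma\!\cdot\!B(\log t) + x^\top\beta)$
  with the published per-tier hazard ratios as $\beta$ truth and a smooth
  baseline ($\gamma = (6, -1, 0.5)$ on the log-age basis — incidence rising
  steeply with age, cases about a decade older than the cohort mean, as
  observed). The inverse transform is vectorised bisection on the age axis,
  which handles any monotone log-cumulative-hazard function.
* **Baseline level.** The intercepts are calibrated by bisection with
  common random numbers against incidence targets, in two modes. `stratum`
  mode gives each region stratum its own intercept calibrated to the
  published stratum rates (132.2 / 20.2 per 100,000 person-years; pooled
  46.2 at 23.2% high-risk). `shared` mode calibrates a single intercept to
  the pooled rate, carrying the region contrast purely through its hazard
  ratio. The distinction matters for parameter-recovery experiments: a
  stratum-specific intercept offset is statistically indistinguishable from
  a region main effect, so fitting a single-intercept model to
  stratum-mode data recovers the region HR times the offset (the published
  stratum-rate ratio, 6.54, is not the published region HR, 6.31).
  Recovery runs therefore use `shared` mode; rate-consistency runs use
  `stratum` mode.
* **Competing risks and censoring.** All-cause mortality is
  piecewise-constant in 5-year age bands at plausible Chinese adult levels
  (config, not hard-coded); loss to follow-up is a small exponential
  hazard; administrative censoring is a uniform window calibrated once so
  that median follow-up is about 11.1 years (development profile; IQR
  close to the published 10.2–12.1) or 13.6 years (external profile).
* **Bookkeeping.** Prior-cancer and missing-BMI flags at the published
  pre-exclusion rates; pathology confirmation (~33% of cases, 92.7% of
  confirmed subtyped as squamous) for the sensitivity filters; a single RNG
  stream per run with the seed recorded on the output.

What the generator does **not** emulate: geographic clustering beyond the
binary region label, within-person covariate dynamics, diagnostic delay,
secular trends in incidence, or real missing-data mechanisms. Passing tests
therefore demonstrate that the estimation and validation machinery is
correct under the stated data-generating process — not that the published
models are correct for real populations.

## What the package's checks do and do not show

The published headline results (external AUCs of 0.822/0.830, internal
0.871–0.883, recalibration pair 1.22/1.97) were computed on private cohort
data and are not reproducible from structure alone; they are never used as
numeric targets. What is checked, end to end: the exclusion cascades
reproduce the published participant accounting exactly; the calibrated
generator reproduces the published incidence rates within Monte-Carlo
error; fitting a tier to a large cohort generated with that tier's
published hazard ratios as truth recovers them within Monte-Carlo error
(the central estimation claim); and the surrounding machinery obeys its
closed forms and invariants (constant-hazard absolute risk, Weibull limits,
recalibration round trips, brute-force metric equivalences, Kaplan–Meier
identities, nested-likelihood ordering, bit-level determinism).

## Problem sizes

The test suite works at deliberately modest scale — cached cohorts of
40,000 (development profile) and 15,000 (external profile), recovery runs
of 150,000, one 1,000,000-row draw for marginal checks — chosen so the full
suite exercises every stage at Monte-Carlo tolerances appropriate to those
sizes. The acceptance script uses 500,000-row cohorts per replicate (two
replicates for the simple and intermediate recovery runs, three for the
full tier, averaging log hazard ratios across replicates) because its
sparsest coefficients — burning-hot tea at ~5% exposure among ~2,400 cases
per replicate — need the extra events for a per-coefficient Monte-Carlo SE
comfortably below the published values' own confidence widths.

## Known limitations

* The recalibration functional form and the discrimination-eligibility
  treatment of competing deaths are reconstructions of under-specified
  procedures, as discussed above.
* Cause-specific hazards assume conditional independence given covariates;
  the Kaplan–Meier "observed risk" used for calibration censors competing
  deaths and so estimates net risk, slightly above the absolute risk being
  validated at old ages — visible as a small upward tilt in calibration
  ratios, inherent to the published validation design.
* Fits with very sparse events near the upper boundary knot can be locally
  non-monotone in the right tail; they are flagged, and the risk integral
  floors the hazard at zero there.
* The region label is binary; within-stratum heterogeneity is not modelled.
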