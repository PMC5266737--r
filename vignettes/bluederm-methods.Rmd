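---
title: "Modeling psoriatic epidermis under blue-light phototherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling psoriatic epidermis under blue-light phototherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bluederm` simulates the cell-population dynamics of a 1 mm^2 column of
psoriatic epidermis during and after blue-light (453 nm) phototherapy.
Keratinocytes are tracked through six differentiation stages — stem cells,
transit-amplifying (TA) cells, growth-arrested cells, spinous cells,
granular cells and corneocytes — in two coexisting lineages, healthy and
diseased. That gives a 12-dimensional state of cell densities
(cells/mm^2) governed by ordinary differential equations with four kinds of
processes:

* **proliferation** (`gamma1`, `gamma2`): self-renewing divisions of stem
  and TA cells;
* **division/differentiation** (`k1a`, `k1s`, `k2a`, `k2s`, `k3`, `k4`,
  `k5`): asymmetric and symmetric divisions of the proliferative
  compartment and the staged maturation of the non-proliferative one;
* **apoptosis** (`beta`): derived from each population's apoptotic index
  `AI` via `beta = AI * k / (1 - AI)`, so that `AI` is the fraction of the
  total outflux lost to apoptosis;
* **desquamation** (`alpha`): shedding of corneocytes from the surface.

Three nonlinearities couple the lineages. Stem cells of both lineages
share a logistic niche: self-proliferation is gated by
`1 - (Psc_h + Psc_d) / (lambda_cap * Psc_max)`, so the summed stem density
can never grow through the psoriatic capacity `lambda_cap * Psc_max`.
Healthy stem rates are additionally scaled by the TA feedback
`omega / (1 + (omega - 1) * ((Pta_h + Pta_d)/Pta_hom)^n)`: at homeostatic
TA density the factor is 1, at zero TA density it reaches the maximal fold
increase `omega = 100`. Diseased stem cells escape this feedback — that is
the modeled hyper-proliferation — but are removed by a Hill-type immune
term `K_p * Psc_d^2 / (K_a^2 + Psc_d^2)`. The diseased granular
compartment is identically zero (parakeratosis: the granular layer is
absent in lesional skin), so diseased spinous cells cornify directly.

The two stable regimes of this system — a ~100,000 cells/mm^2 all-healthy
state and a ~217,000 cells/mm^2 diseased-dominated state — make it
bistable, and `phase_diagram()` maps which per-session fluences can push
the system from one basin to the other.

## Blue-light action

Irradiation enters through three fluence-dependent factors, recomputed each
calendar day from that day's applied fluence `F` (J/cm^2):

* `bl_proliferation_factor()`: `a_gamma * exp(b_gamma * F)`, clamped to
  [0, 1]; multiplies the self-proliferation rates. Defaults `a_gamma = 1`,
  `b_gamma = -3.4e-3` cm^2/J.
* `bl_differentiation_factor()`: `c_k - a_k * exp(b_k * F)`, clamped to
  [0, 1]; with the default coefficients (3.46, 2.46, 0.0194) it equals 1
  at `F = 0` and hits 0 near `F = 17.6` J/cm^2. The clamp is a package
  decision: the raw expression goes negative above the root, and negative
  rates are meaningless. In the selected mechanism this factor is never
  applied, so the clamp only matters for hypothesis-screen variants.
* `theta_beta_of_fluence()`: an additive apoptosis increment, 0 below
  500 J/cm^2, 0.039/d on [500, 750) and 0.05/d from 750 up. The published
  wording ("between 500 and 750", "above 750") leaves the boundaries open;
  we close them on the left, so a 500 J/cm^2 session is already cytotoxic,
  consistent with the reported sharp severity drop *at* 500 J/cm^2.

On non-treatment days `F = 0` and all factors are neutral. The factors are
parameterized against incident dose; setting `fluence_absorbed = TRUE`
multiplies the calendar fluence by the epidermal energy absorbance
`xi_abs = 0.579` first. The absorbance is carried as a parameter because
the source optical model is unpublished, and nothing in the published
equations consumes it — the option is therefore off by default.

## Mechanism hypotheses

Which rates the factors multiply is itself the scientific question the
model was built to screen. `hypothesis_case()` encodes thirteen
combinations: case 1 applies the proliferation factor to `gamma1`/`gamma2`
only; cases 2–13 additionally or instead perturb division and
differentiation rates. The screen (`screen_cases()`) summarizes each case
by three daily flux aggregates — proliferative capacity (sum of gamma
fluxes), differentiation capacity (sum of k fluxes) and immune capacity
(the killing flux). These operational definitions are our interpretation
of otherwise unlabeled screen axes, so tests assert only directions of
change. Case 1 is the mechanism the screen selects (division-only cases
fail to suppress the proliferative compartment), and it is the package
default everywhere.

The "increase" cases posit rates that *rise* under irradiation, which the
bounded differentiation factor cannot express and for which no functional
form is published. We use the reciprocal `1/bl_differentiation_factor(F)`,
capped at `theta_k_max = 10`; this is flagged as an interpretation, and
`theta_k_direction = "off"` recovers the factor-free limit (under which
cases 1 and 13 coincide — a tested invariant).

## Equation conventions

The typeset source equations contain four places where fluxes do not
balance; integrating them literally collapses compartments that the same
source's own steady state requires to be full. Both conventions are
implemented. `"as_printed"` evaluates the equations literally.
`"flux_consistent"` (default) applies four corrections, each justified by
a steady-state flux audit at the published initial state (the audit is
itself exported, `flux_audit()`, and re-derived independently in the test
suite):

1. the stem-to-TA influx `(k1a + 2 k1s) * theta_k * Psc` enters the TA
   equation with a positive sign (divisions produce TA cells; the printed
   minus would make the diseased TA balance miss by ~740 cells/mm^2/day
   instead of ~3);
2. symmetric TA divisions deliver **two** growth-arrested cells:
   `(k2a + 2 k2s)` rather than `(k2a + k2s)` (audit: influx 19,394 vs
   required ~19,968 — the printed variant gives 17,449);
3. the diseased spinous equation uses the diseased `k4_d`, not the healthy
   `k4_h` (a single-character typo);
4. the diseased corneocyte influx is `k4_d * theta_k * Psp_d`. As printed
   it is `k5_d * Pgc_d`, which is identically zero because the diseased
   granular pool is empty — corneocytes would desquamate to extinction.
   Routing spinous cells directly to the cornified layer is exactly the
   parakeratosis the empty granular pool encodes (audit: influx 19,947 vs
   desquamation 19,408).

With these corrections every diseased compartment's residual at the
published initial state is below 5% of its gross influx, i.e. the state is
the near-fixed point it is described to be.

Two parameters needed by the equations have no published value.
`k_m1_d`/`k_m2_d` (diseased back-conversion) default to the healthy
`1e-6`/d by symmetry. `Pta_hom` (homeostatic TA density) is calibrated by
`calibrate_pta_hom()` so that the untreated all-healthy steady state
totals 100,000 cells/mm^2, the literature density of healthy epidermis;
the frozen result, 6,678.26 cells/mm^2, ships in the defaults and the
calibration (root finding over a 50,000-day settling integration; the
slowest healthy modes have time constants of thousands of days) can be
re-run by the user. The published diseased rates also differ from the
healthy-rate-times-fold-change products they are described as (ratios
~3.5 and ~4.5 rather than 4 and 5); the printed values are the default and
`derived_diseased_rates(mode = "product")` exposes the product rule for
transparency.

## Treatment protocols

A protocol is an ordered list of phases (duration, cadence, per-session
fluence, session time, CW/PW mode, duty cycle) plus follow-up.
`build_calendar()` expands it to a per-day fluence sequence; the model
applies each day's factors for the whole day, because the clinical effect
is parameterized per treatment day, not per 30-minute session. Pulse
structure (peak intensity `I_p = I_av / duty_cycle`) is therefore metadata:
CW and PW protocols with the same calendar are *identical model inputs*,
which is the mechanism behind the null result for irradiation mode and
intensity, and is asserted as a test rather than discovered by it. The
three-sessions-per-week cadence defaults to days 1/3/5 of each 7-day block
(Mon/Wed/Fri); the clinical pattern is not documented, so any 3-of-7
pattern can be configured. `pfaff_protocol()` builds the reference
regimen: 28 daily sessions then 8 weeks at 3 sessions/week, 90 J/cm^2 per
30-minute session.

## Numerics

Rates are piecewise constant in time, so integration proceeds segment by
segment: consecutive days with equal fluence are fused, and `lsoda`
(stiff-capable, via deSolve, right-hand side compiled in C) is restarted
at every fluence switch, keeping the discontinuities sharp. Tolerances are
`rtol = 1e-8`, `atol = 1e-6` cells/mm^2; excursions below zero smaller
than `atol` are clipped at segment boundaries, anything larger is an
error. A pure-R reference right-hand side (`epidermis_rhs()`) is kept and
tested for exact agreement with the compiled one across random states,
fluences, cases and conventions.

Scan defaults: `fluence_scan()` and `phase_diagram()` use 12-week daily
continuous-wave courses (the phase diagram adds a 12-week relaxation
before classifying the endpoint by `Psc_h > Psc_d`); `length_scan()`
covers 4–28 weeks in 4-week steps. The relaxation length is configurable
since the figure-generating value is not documented.

## Sensitivity analysis

`mpsa()` implements the multi-parametric sensitivity analysis: Latin
hypercube sampling of 34 continuous parameters, one treatment simulation
per sample, squared-error costs against the nominal run's end-of-treatment
outputs (12 densities plus severity), classification into acceptable and
unacceptable samples, and a two-sample Kolmogorov–Smirnov statistic `D`
per parameter and output. Design choices where the method description is
silent, all configurable: sampling bands are ±50% around nominal values;
the acceptability threshold is the per-output cost median (balanced
classes); the reference output is the end-of-treatment state under the
reference protocol; the hypercube is seeded. Apoptosis rates are not
sampled directly — they are derived from the sampled apoptotic indices and
division rates, so they co-vary as the model structure dictates. The
default sample count is 5,000 (the original analysis used 500,000; 5,000
keeps the full analysis under three minutes on one CPU and the
Kolmogorov–Smirnov noise floor near 0.04, well below the 0.3 reporting
threshold). At these settings the `D > 0.3` set is small and consists of
diseased TA proliferation/division parameters — consistent with the
qualitative finding that proliferation-related parameters dominate, though
the exact membership of the set depends on the unpublished sampling ranges
and threshold and is asserted only qualitatively.

`lpsa()` complements this with normalized central-difference local
sensitivities `(dy/dtheta)*(theta/y)` at the nominal point (default
perturbation 1%).

## Dose–response calibration

The blue-light coefficients were originally estimated from an in-vitro
keratinocyte irradiation experiment that is available only as a figure, so
the package provides both a synthetic stand-in and the fitting machinery.
The forward model (`culture_response()`) is our documented
interpretation of the assay: a culture growing exponentially at rate
`r0` (default `log(2)`/day, a 24 h doubling time) for `T = 3` days, with
growth scaled by the proliferation factor, read out as end-point density
relative to the untreated control. `synth_dose_response()` adds Gaussian
noise (default sd 0.02) to replicates on the assayed fluence grid
{0, 33, 66, 100} J/cm^2; `fit_bl_coefficients()` recovers `a_gamma > 0`,
`b_gamma < 0` by bounded nonlinear least squares. Parameter-recovery tests
(100 seeded replications) hold the median error of `b_gamma` under 10% at
that noise level. Fitting the differentiation-factor coefficients with the
same machinery is possible in principle but not wired in by default, since
the selected mechanism never uses that factor.

What the synthetic generator does *not* emulate: plating effects,
saturating growth, replicate correlation, or any fluence–wavelength
interaction. Passing recovery tests therefore show the estimator is
consistent under the package's own assay model, not that the published
coefficients are re-derivable from raw data.

## Severity index

`lpsi_series()` maps total density to the local psoriasis severity index.
The published formula subtracts the relative density change from the
baseline score, which *raises* severity when density falls — the opposite
of the positive density–severity correlation the mapping is explicitly
built on, and of every reported trend. The package default is therefore
the proportional form `LPSI_i = LPSI_0 * PTot_i / PTot_0` (clamped at 0),
and the literal form is retained under `sign_convention = "as_printed"`
for audit. The default anchor `lpsi0 = 5.17` is the reported baseline of
the high-intensity clinical arm.

## Known limitations

* No spatial structure: the epidermis is a well-mixed column; no optical
  transport, only the single absorbance constant.
* No immune-cell dynamics beyond the fixed Hill killing term, although
  blue light is known to also act on immune cells.
* Single wavelength (453 nm), skin types 1–3 only.
* The clinical severity comparison is shape-only: the published curves are
  figures, so tests assert decrease-during-treatment, minimum inside the
  treatment window, and monotone relapse, not point values.
* Figure-only quantities (screen capacities, exact scan curves) are
  checked as properties, not numbers.
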