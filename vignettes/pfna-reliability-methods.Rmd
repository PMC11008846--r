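---
title: "Probabilistic failure assessment of PFNA-stabilized intertrochanteric fractures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic failure assessment of PFNA-stabilized intertrochanteric fractures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfnarel)
```

## The problem

Intertrochanteric fractures of the proximal femur are commonly fixed with a
proximal femoral nail antirotation (PFNA): an intramedullary nail with a
helical blade seated in the femoral head. The dominant mechanical failure
mode is *cut-out* — migration of the blade through the head as the
surrounding trabecular bone yields. Cut-out risk rises with the compressive
strain in the proximal trabecular bone, which in turn is driven by two
patient-specific quantities that are both poorly known at the individual
level: the apparent bone mineral density (BMD, g/cm³) of the trabecular
bone, and the hip contact load during daily activity, expressed in
body-weight multiples (BW; one BW is taken as roughly 750 N).

Deterministic finite-element (FE) analyses answer "what strain does *this*
bone see under *this* load"; they cannot answer "how likely is this
construct to fail given realistic variability in bone quality and in how
much weight the patient actually bears". This package implements the
probabilistic layer: a closed-form response surface for the strain, and a
reliability computation that turns input uncertainty into a probability of
failure (PoF).

## The strain surrogate

The peak compressive strain `S` (dimensionless fraction) in the proximal
trabecular bone is approximated by a bivariate quadratic:

```
S(BMD, BW) = 1e-3 * (4.09 - 17.66*BMD + 2.80*BW - 2.35*BMD*BW
                     + 15.67*BMD^2 - 0.05*BW^2)
```

available as `published_model()`. The coefficients are stored exactly as
reported (printed values plus a separate `1e-3` scale), so the model is
bit-faithful to its source. The surrogate was trained on 100 FE simulations
with designs drawn by Latin hypercube from BMD ~ N(0.5, 0.175) g/cm³ and
BW ~ N(2, 0.4); evaluations outside the mean ± 3 sd envelope of those
distributions warn, because the polynomial extrapolates badly there — it can
even go negative at very low loads, and, being convex in BMD, it re-crosses
any yield level at nonphysical densities above ~1.3 g/cm³. The boundary
solver `failure_boundary_bmd()` therefore returns *all* non-negative roots
and leaves range restrictions to the caller.

Within the envelope the surrogate behaves as the mechanics suggest: strain
increases linearly-ish with load (`dS/dBW > 0` everywhere relevant) and
decreases nonlinearly with BMD, with diminishing effect above roughly
0.6 g/cm³.

`fit_response_surface()` refits the same six-coefficient form by ordinary
least squares (`stats::lm`) and reports SSE, R², adjusted R² and
RMSE = sqrt(SSE/(n − p)). A constant response (SST = 0) is reported as
R² = 0 with a warning rather than NaN.

The density–modulus laws (`cortical_modulus()`, `trabecular_modulus()`;
affine for cortical bone, 6950·ρ^1.49 MPa for trabecular bone) document the
material model behind the FE stage. They are provided for provenance and are
not part of the PoF computation — the surrogate already absorbs the material
behaviour.

## The reliability model

Failure is compressive yielding of the trabecular bone. The capacity is the
yield strain `Y ~ N(0.0085, 0.0010)` (0.85% ± 0.10%, `yield_criterion()`);
the demand is `S`. With the performance function `Z = Y − S`,

```
mu_Z = mu_Y - mu_S,  sigma_Z = sqrt(sigma_S^2 + sigma_Y^2),
beta = mu_Z / sigma_Z,  PoF = 1 - pnorm(beta).
```

Everything therefore reduces to the first two moments of `S` under
`BMD ~ N(mu_b, sigma_b)`, `BW ~ N(mu_w, sigma_w)`, independent. Three
analytic modes are provided, always computable side by side:

* **`paper_termwise`** (replication mode, the default). Each regressor
  (BMD, BW, BMD·BW, BMD², BW²) is reduced to a mean and sd with the exact
  closed forms for products and squares of independent normals
  (`product_moments()`, `square_moments()`), and the five terms are then
  combined *as if they were independent*:
  `sigma_S^2 = sum a_i^2 sigma_i^2`. This deliberately drops the
  covariances among the derived terms (BMD and BMD² are strongly
  correlated), and for the published coefficients it overstates `sigma_S`
  by roughly 65% at the reference scenario. It is retained as the default
  because it is the recipe that reproduces the published headline PoF
  values; treat it as a documented convention, not a recommendation.
* **`taylor_first_order`**. Mean-value FOSM: `mu_S = S` at the means,
  `sigma_S^2 = (dS/dBMD)^2 sigma_b^2 + (dS/dBW)^2 sigma_w^2`. Exact for a
  linear surrogate; drops all second-order variance.
* **`exact_moments`** (recommended for new analyses). Exact mean and
  variance of the quadratic form: with independent inputs,
  `E[X^i W^j] = E[X^i]E[W^j]`, and normal raw moments up to order four
  close `E[S]` and `E[S^2]` in closed form, covariances included.

For any linear surrogate the three modes coincide exactly — a property the
test suite asserts to 1e-12 — and `strain_moments_exact()` is itself checked
against 10⁶-draw Monte Carlo on a COV grid, within four standard errors.

One approximation remains even in `exact_moments`: the final tail step
`PoF = 1 − pnorm(beta)` presumes `Z` is normal, while a quadratic in normals
is not. At the reference scenario (50–64 years, normal walking, COV 0.1/0.1)
the analytic tail and a 10⁶-draw Monte Carlo estimate differ by a few parts
in 10⁴ of probability — larger than the Monte Carlo standard error, small
compared to every decision threshold discussed here. `pof_monte_carlo()`
quantifies this gap whenever it matters; it deliberately evaluates the
polynomial on raw, untruncated normal draws (negative BMD included) so that
it tests the same distributional assumptions the analytic modes make.
Truncated sampling is available as an explicit opt-in for sensitivity
analyses only.

## Scenarios

Mean BMD by age group — 50–64: 0.3375, 65–79: 0.2875, ≥80: 0.275 g/cm³ —
and mean load by activity — normal walking 2.38, up stairs 2.51, down
stairs 2.60, standing up 1.90, sitting down 1.56 BW — are built in
(`age_groups()`, `activities()`). Uncertainty enters through coefficients of
variation: `sigma = mean × COV`, swept over 0.1–0.9 in steps of 0.1 on both
axes (`sweep_pof()`), 3 × 5 × 9 × 9 = 1215 cells. A 5% PoF reporting
threshold (configurable) flags the conventional "acceptable risk" regime.

```{r headline}
headline_numbers()
```

Two structural properties of the sweep are worth stating precisely:

* PoF is monotone non-decreasing in the activity load mean at fixed
  everything else. This holds across the whole grid: a larger `mu_w` raises
  `mu_S`, and (because sd is tied to the mean through the COV) also raises
  `sigma_S`; both push PoF up while `mu_S < mu_Y`, which is everywhere the
  case here (max PoF ≈ 40%).
* PoF is **not** globally monotone in the age-group BMD mean, and this is a
  real feature of the COV parameterisation, not a numerical artifact. A
  lower BMD mean raises the strain mean — but it also *shrinks*
  `sigma_BMD = mean × COV`. At low COV_BMD the mean effect dominates and
  the intuitive ordering (older group ⇒ higher PoF) holds; at high COV_BMD
  the spread effect dominates and the ordering reverses in a substantial
  fraction of cells (it persists, attenuated, in `exact_moments` mode). The
  test suite asserts the ordering at COV_BMD = 0.1 and the existence of the
  reversal at COV_BMD = 0.9. Any claim that PoF always decreases with BMD
  implicitly assumes the sd is held fixed, which the COV convention does
  not do.

## The virtual experiment

`generate_virtual_experiment()` stands in for the FE campaign: design points
by Latin hypercube from the stated distributions, responses from a truth
surrogate plus homoscedastic Gaussian noise. The default noise sd, 6.57e-4
strain, is the only free choice; it is derived from the reported residual
sum of squares of the original fit (sqrt(4.316e-5 / 100)). No residual
structure beyond i.i.d. Gaussian is claimed anywhere, so the simplest model
consistent with that SSE is used, and the sd is configurable.

Two published fit statistics cannot be reconciled with this (or any
standard) setup: the reported RMSE of 0.0011 is inconsistent with
SSE = 4.316e-5 at n = 100 under any usual RMSE definition, and the reported
R² of 0.9334 is unattainable under the stated design distributions — the
exact strain sd under the design is 1.48e-3, giving a population
R² = sigma_S² / (sigma_S² + noise²) ≈ 0.835, and seeded replicates scatter
between roughly 0.75 and 0.90. The generator keeps the stated conditions
rather than retuning the noise to hit the printed R²; the parameter-recovery
tests assert the envelope the generator actually produces, and the recovery
experiment (`parameter_recovery_experiment()`) shows the least-squares
coefficients are unbiased under it.

What the generator does *not* emulate: FE discretisation error (spatially
correlated, not i.i.d.), contact nonlinearity, specimen-to-specimen geometry
variation, or any heteroscedasticity of the FE residuals. Passing tests
therefore demonstrate the statistical pipeline is correct under its own
generative model, not that the surrogate form is adequate for real femora.

Sampled BMD values below 0.01 g/cm³ are clipped to 0.01 (an FE input must be
physical) with a reported count; this clipping applies only in the
generator, never in the reliability oracles.

## Numerical choices and conventions

* Strain is a fraction everywhere internally; percent appears only in
  formatted output and in the acceptance report (which reports PoF in %).
* Latin hypercube placement is uniform-within-stratum (via `lhs::randomLHS`)
  with a midpoint option; one integer seed makes the whole matrix
  reproducible.
* Degenerate cases are warnings, not errors: sigma_Z = 0 yields the
  step-function PoF limit; SST = 0 yields R² = 0.
* `failure_boundary_bmd()` uses the closed-form quadratic solve (linear
  fallback when the BMD² coefficient is zero) and returns roots that satisfy
  `S = yield` to 1e-10; grid classification (`classify_region()`) is
  consistent with those roots to grid resolution.
* Problem sizes in the test suite: Monte Carlo oracles use 10⁶ draws at
  fixed seeds; parameter recovery uses 100 replicates of n = 100; sweeps use
  the full 1215-cell grid. These sizes give 4-standard-error moment checks
  and sub-percent PoF resolution.

## Known limitations

* The term-wise default reproduces the published numbers but is not the
  best available estimator; use `exact_moments` for new work.
* All inputs are treated as mutually independent normals; correlated BMD–BW
  (e.g. frailty) is out of scope.
* The FOSM tail assumes normal `Z`; for PoF below ~1e-4 prefer
  `pof_monte_carlo()` with a large `n`.
* No design-point (FORM/SORM) search, no time-variant reliability, no
  fatigue: the analysis is a single-load-event yield check.
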