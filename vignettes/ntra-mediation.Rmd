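---
title: "Trimodal radiodensity modelling and mediation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimodal radiodensity modelling and mediation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntramed)
```

## The trimodal radiodensity model

A mid-thigh CT cross-section, after calibration and soft-tissue
segmentation, gives a per-subject distribution of radiodensity values in
Hounsfield units over the range −200 to 200 HU. The model treats this
distribution as a quasi-probability density summing three skew-Gaussian
components, one per canonical soft-tissue type:

$$f(x) \;=\; \sum_{i=1}^{3} \frac{N_i}{\sigma_i\sqrt{2\pi}}
  \, e^{-\frac{(x-\mu_i)^2}{2\sigma_i^2}}
  \, \operatorname{erfc}\!\left(\frac{\alpha_i\,(x-\mu_i)}{\sigma_i\sqrt{2}}\right)$$

with fat centred deep in the negative range, loose connective
(water-equivalent) tissue near 0 HU, and lean muscle in the positive
range. Since $\operatorname{erfc}(t) = 2\Phi(-t\sqrt{2})$, each term is
$N_i$ times a skew-normal density with location $\mu_i$, scale $\sigma_i$
and shape $-\alpha_i$. Two identities follow and are enforced by tests:
the value at $x=\mu$ is $N/(\sigma\sqrt{2\pi})$ for *any* skewness
(`erfc(0) = 1`), and the integral over the real line is exactly $N$
(skew-normal normalization is shape-free), which ties the amplitude to
the voxel count of its tissue. With this sign convention $\alpha > 0$
produces a tail toward *lower* HU — the inward slope of the muscle peak
under myosteatosis — and the sampled third central moment has sign
$-\operatorname{sign}(\alpha)$.

The connective component is structurally symmetric: its skewness is not a
parameter at all, leaving eleven free values
(`fat_N, fat_mu, fat_sigma, fat_alpha, conn_N, conn_mu, conn_sigma,
muscle_N, muscle_mu, muscle_sigma, muscle_alpha`). Locations must order
as fat < connective < muscle.

### Parameters, units, defaults

| parameter | unit | meaning | fit bounds |
|---|---|---|---|
| `N` | mass units (see *scale*) | integrated component mass ∝ voxel count | ≥ 0 |
| `mu` | HU | component location | fat −200…0, conn −60…50, muscle 30…120 |
| `sigma` | HU | component width | 0.5…60 |
| `alpha` | – | skewness | −10…10 |

The `mu` windows widen the canonical tissue domains (fat −200…−10,
connective −9…40, muscle 41…200 HU) so a peak near a domain edge is not
clipped; they overlap, and the ordering invariant is asserted after the
fit rather than imposed as a constraint. The `alpha` cap at |10| prevents
erfc-driven mode collapse into a half-Gaussian; `sigma`'s floor of 0.5 HU
(half a default bin) marks degenerate fits, which are flagged via
`degenerate` rather than raised as errors.

### Histogram convention and the amplitude scale

Voxels are binned into half-open 1-HU bins $[e, e+1)$ over $[-200, 200)$;
the value 200 itself is outside the range and discarded (with a count of
discards reported). Bin centers sit at edge + width/2.

The fit minimizes ordinary least squares on bin heights,
$\sum_k (h_k - f(x_k))^2$, where $h_k$ rescales counts so that the
histogram area equals a chosen `scale` — the model's total-mass unit. The
amplitudes are identifiable only *up to* this overall mass: a histogram of
$n$ voxels carries no information about the absolute unit in which the
cohort reports amplitudes like "muscle N ≈ 78". The package therefore
makes `scale` explicit: the default (`sum(counts) * bin_width`) fits raw
counts, and parameter-recovery runs pass the generating total mass
(181.6 for the baseline reference parameters) so recovered amplitudes are
comparable to the truth. This is a deliberate resolution of an
under-determined convention; shape parameters (`mu`, `sigma`, `alpha`)
and amplitude *ratios* are invariant to it.

### Optimization

The objective is minimized with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, finite-difference Jacobian) — the contract is the
minimized least-squares objective, not any particular algorithm. Starting
values are moment-based per tissue domain: count-weighted mean and SD
(floored at 1 HU), amplitude from the peak height times
$\sigma\sqrt{2\pi}$, and skewness −2 / 0 / +2 for fat / connective /
muscle. An empty domain yields an empty component (N = 0, `mu` at the
domain midpoint, `sigma` = width/6). Five starts are used by default: the
moment start plus four jitters (amplitudes and widths × U(0.7, 1.4),
locations ± 5 HU, skewness ± 1), seeded explicitly; the best objective
wins. Refitting from a recovered optimum changes the objective by less
than 1e−8 relative (idempotence, tested).

On histograms of $10^5$ voxels sampled at the reference parameters, the
optimizer reliably reaches an SSE *below* that of the generating
parameters; remaining estimation error is sampling noise of the
unweighted least-squares estimator, largest for the two skewness
parameters. The test suite therefore checks locations to 1 HU per run and
per-parameter *median* relative error below 5% across 20 seeds — the
regime in which this estimator is accurate — rather than a per-seed bound
on every parameter.

## The mediation pipeline

The pipeline asks whether radiodensity parameters mediate the
longitudinal relationship between a five-level self-reported physical
activity score (PA, treated as numeric 1–5, as is standard for Likert
exposures in this literature) and four lower-extremity-function tasks
measured about five years later. All models are ordinary least squares
with intercept on complete cases (per-model deletion, counts recorded),
reporting raw coefficients, standard errors, t-based p-values and
standardized coefficients $\beta = b \cdot \mathrm{sd}(x)/\mathrm{sd}(y)$.
Both scales are kept because the two answer different questions:
attenuation percentages are computed on the standardized scale (which
reproduces the published worked example from published $\beta$s), while
bootstrap effects are raw-scale (Newtons, m/s, seconds).

1. **Total effect** (4 tests): `LEF_fu ~ pa + age + sex + bmi + LEF_base`.
2. **Mediator screen** (11 tests): each parameter
   `~ pa + age + sex + bmi`; mediators are the parameters whose activity
   coefficient survives Holm–Bonferroni across all eleven tests. The
   family is the full set of eleven (not per-tissue blocks) — the most
   conservative of the defensible groupings.
3. **Outcome models** (mediators × 4 tests): `LEF_fu ~ mediators +
   age + sex + bmi + LEF_base` (no exposure).
4. **Full models** ((1 + mediators) × 4 tests): adds `pa`; attenuation is
   $100(\beta_{\text{full}} - \beta_{\text{prior}})/\beta_{\text{prior}}$,
   undefined (flagged `NA`) when the prior coefficient is zero.

Holm–Bonferroni uses the stepdown rule with the ≤ boundary convention
(p = α with m = 1 is rejected); rejection decisions delegate to
`stats::p.adjust(method = "holm")`, with per-rank thresholds
$\alpha/(m - k + 1)$ reported alongside. Sex is coded 0 = female,
1 = male; coefficient signs involving sex are coding-dependent.

An empty screen result short-circuits steps 3–4 and the bootstrap into a
structured "no mediation testable" report — the step-1 and step-2 tables
are still emitted.

### Bootstrap effects

For each task, the specific indirect effect of mediator $j$ is the
product $a_j b_j$: $a_j$ the activity coefficient from the step-2 model,
$b_j$ the mediator coefficient from the step-4 model. The total indirect
effect is defined as $\sum_j a_j b_j$, so point-estimate additivity holds
by construction, and the direct effect is the activity coefficient of the
step-4 model. Confidence intervals are percentile intervals over B
subject-resamples (default B = 5000; bias-corrected intervals behind
`bias_corrected = TRUE`); a resample with a rank-deficient design is
discarded and redrawn, capped at 1% of B. Significance means the interval
excludes zero. Published analyses of this design report total indirect
effects that do not exactly equal the sum of the printed specifics
(rounding or a different totalling convention); this package enforces
additivity.

## The synthetic cohort generator

`generate_cohort()` emulates the marginal structure of the
access-restricted cohort behind this design: five-level activity
frequencies 39.8/16.7/7.7/18.3/17.5%, age 74.9 ± 4.8 y, 58% female,
BMI 27.3 ± 4.2, the published baseline/follow-up LEF moments and
follow-up radiodensity-parameter moments (`cohort_reference_marginals()`).
Planted paths are specified on the *standardized* scale and converted to
raw units via the nominal marginal SDs (the activity score's SD is the
exact categorical value 1.57, not the rounded 1.6); residual SDs are set
to $\mathrm{sd}\sqrt{1-\sum\beta^2}$ so marginal SDs approximate their
nominal values. Covariate effect sizes default to signs consistent with
the published fitted models (age degrades gait and strength and slows
up-and-go; BMI raises fat and connective amplitudes) with round
illustrative magnitudes — they are scenery, not estimates. Timed
up-and-go paths are sign-flipped throughout (higher = worse).

`muscle_mediation_scenario()` plants mediation only through muscle
amplitude and location: standardized a-paths (0.10, 0.12), b-paths per
task GSF (0.30, 0.10), GSN (0.27, 0.12), STR (0.33, 0.10),
TUG (−0.08, −0.16), and direct effects (0.14, 0.14, 0.07, −0.11). These
magnitudes mirror the published step-2/step-4 coefficient ranges
(activity explains a small share of mediator variance, standardized
screen coefficients near 0.08–0.12) while keeping every indirect-effect
z-value clearly above the significance boundary at n = 3000 — notably the
TUG b-path for muscle amplitude is set to −0.08 rather than the published
≈ −0.05, whose product interval would sit on the boundary and make the
qualitative all-intervals-exclude-zero pattern a coin flip rather than a
property of the design.

With `noise_scale = 0` the cohort is purely structural: step-1 and step-2
regressions recover `direct + total indirect` and the raw a-paths exactly.
Note that zero *mediator* noise makes mediators exact linear functions of
exposure and covariates, so models containing both are rank-deficient by
construction; per-equation overrides (`mediator_noise_scale`,
`outcome_noise_scale`) allow exact checks of each step separately.

What the generator does **not** emulate: correlations among the eleven
mediators beyond those induced by shared exposure/covariate paths (the
published marginals carry no covariance information, so the residual
covariance is diagonal — configurable in principle, flagged here);
attrition between timepoints; self-report measurement error; non-Gaussian
covariate marginals. Passing tests therefore demonstrate correctness of
the estimators under the stated generating model, not robustness to those
real-data features.

## Problem sizes and numerical choices in the test suite

The suite exercises: quadrature mass checks over 100 random parameter
draws (1e−6 relative); parameter recovery at $10^5$ voxels × 20 seeds;
OLS versus a hand-coded normal-equations oracle on 20 random designs
(1e−8); Holm versus a brute-force stepdown on 1000 random p-vectors;
the end-to-end planted scenario at n = 3000 with B = 1000 (scaled from
the B = 5000 analysis default); and bootstrap calibration over 200
simulated datasets (n = 400, B = 250 each) — type-I rate of the indirect
interval accepted in 1–11% at a planted zero a-path, and coverage of a
planted nonzero indirect effect accepted in 90–98.5% at nominal 95%.
These sizes are the package's chosen verification regime; all random
draws are explicitly seeded, and `erfc` is evaluated as
`2 * pnorm(-t * sqrt(2))` to stay in well-tested tail code.

## Known limitations

- Amplitude units require an external mass scale (above); comparisons of
  `N` across subjects are meaningful only at a common scale convention.
- The mediation estimators are associational: no exposure–mediator
  interaction, sensitivity analysis or counterfactual decomposition.
- Attenuation on rounded published coefficients reproduces the published
  GSF/GSN/STR percentages exactly; the TUG pair gives −20.5% against a
  published −20.3% computed from unrounded coefficients — a rounding
  artefact, documented rather than patched.
- Histogram input assumes calibrated HU values; segmentation and
  calibration are upstream of this package.
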