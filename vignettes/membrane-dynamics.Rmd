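---
title: "Spin-label EPR analysis of membrane molecular dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-label EPR analysis of membrane molecular dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprdyn)
```

## The measurement this package models

Nitroxide spin labels — stearic acids carrying a doxyl group at carbon 5
(5-SASL) or carbon 16 (16-SASL) — intercalate into lipid membranes and
report, through their X-band EPR spectra, on the motion of the acyl chains
around them. 5-SASL sits near the polar headgroups; 16-SASL reports on the
hydrophobic core. Spectra are recorded as first derivatives of the
absorption versus magnetic field, and two regimes produce two distinct
spectral anatomies:

* **Fast motion** (16-SASL in a fluid membrane): motional averaging leaves
  three sharp lines from the ¹⁴N hyperfine coupling (mI = +1, 0, −1, the
  low-field line first). The analysis reads off the peak-to-peak width of
  the central line, ΔH₀, and the three peak-to-peak amplitudes h₊, h₀, h₋.
* **Restricted anisotropic motion** (5-SASL near the headgroups): the
  spectrum shows an outer splitting 2A′∥ (global low-field maximum to global
  high-field minimum) and an inner splitting 2A′⊥ (the characteristic inner
  extrema pair).

From these six quantities the standard membrane-dynamics descriptors
follow:

$$a_0 = \frac{A'_\parallel + 2A'_\perp}{3}, \qquad
  S = 0.5407\,\frac{A'_\parallel - A'_\perp}{a_0}$$

$$\tau_{2B} = 6.51\cdot 10^{-10}\,\Delta H_0
  \left(\sqrt{h_0/h_-} - \sqrt{h_0/h_+}\right)\ \mathrm{s}, \qquad
  \tau_{2C} = 6.51\cdot 10^{-10}\,\Delta H_0
  \left(\sqrt{h_0/h_-} + \sqrt{h_0/h_+} - 2\right)\ \mathrm{s}$$

S is the dynamic orientational order parameter (1 = maximally ordered, 0 =
maximally disordered); τ₂B and τ₂C are rotational correlation times for
motion about and perpendicular to the chain's long axis — lower values mean
greater motional freedom, i.e. higher local fluidity.

**Unit convention.** The τ prefactor assumes ΔH₀ in gauss. Extracted
features carry ΔH₀ in mT, and `correlation_times()` converts (1 mT = 10 G)
by default; this places τ on the 10⁻¹⁰–10⁻⁹ s scale expected for membrane
spin labels. The convention is explicit (`unit` argument) because published
presentations of the formula often leave the field unit implicit.

## Forward models with exact ground truth

Raw spectra from temperature-series experiments on chloroplast membranes
are rarely deposited, so the package ships simulators whose inverse is
analytically known, making the entire chain simulate → extract → compute
testable.

**Fast motion** (`simulate_fast_motion()`): three first-derivative lines of
equal integrated intensity, centred at `center_field − mI·aN`, with the
peak-to-peak width law ΔH(mI) = A + B·mI + C·mI². For area-normalised
Lorentzian lines the derivative amplitude scales as 1/ΔH², so the amplitude
ratios in the τ formulas collapse to width ratios and

$$\tau_{2B}^{\mathrm{true}} = 6.51\cdot10^{-10} \cdot (-2B)\cdot 10, \qquad
  \tau_{2C}^{\mathrm{true}} = 6.51\cdot10^{-10} \cdot (2C)\cdot 10$$

(`ground_truth_tau()`; widths in mT, hence the factor 10). This identity is
exact only for Lorentzian lines, so the oracle refuses Gaussian parameter
sets. Field modulation is not convolved in: the 0.1 mT modulation of a
typical acquisition is treated as already folded into the effective widths.

**Anisotropic** (`simulate_anisotropic()`): a phenomenological
superposition of an axially split derivative-Lorentzian doublet and an
optional narrow central component. The doublet's outer lobes supply the
outer extrema and its inner lobes the inner pair, with the canonical sign
pattern (low-field minimum, high-field maximum). Two internal parameters —
the doublet half-separation and the doublet linewidth — are calibrated by a
fixed-point iteration against the package's *own extraction path* until the
realised splittings match the requested 2A′∥ and 2A′⊥ to a quarter grid
step; geometries that cannot produce four distinct extrema raise an error.
Calibrating through the extraction path (including baseline correction)
rather than against an idealised formula is what makes the round trip exact
by construction. The model is *not* a rigid-limit powder average: no
g-anisotropy, no orientation distribution, no slow-motion lineshape theory.
Its only contract is the realised extrema geometry, which is exactly what
the order-parameter formula consumes.

A design note: a doublet with a *freely chosen* linewidth cannot satisfy
both requested splittings, because for two derivative lines at ±d with
width w the outer separation is 2d + w and the inner is 2d − w. The
calibration therefore treats the doublet width as internal (≈ A′∥ − A′⊥),
and `component_width` parameterises the central component only.

Noise is additive, Gaussian and independent per point; baselines are
linear. That is deliberately minimal: enough to stress the feature
extraction without inventing instrument physics. The default field window
(12 mT centred on 335 mT, X-band) is pure convention.

## Feature extraction: numerical choices

* **Baseline**: a straight line fitted through the outer 5% of points at
  each field edge is subtracted (idempotent). A warning fires if the edge
  windows contain structure that noise cannot explain — the signature of
  lines leaking into the fit.
* **Smoothing**: off for noiseless synthetic data; for noisy data a
  Savitzky–Golay filter (window 5, order 2) is applied identically to every
  spectrum of a series, so series remain comparable.
* **Peak selection** (fast motion): noise can split one physical lobe into
  several raw local maxima, so the three lines are chosen by topographic
  prominence, not raw height; each line pairs its positive lobe with the
  deepest negative lobe before the next selected line.
* **Inner-extrema rule** (anisotropic): the inner pair brackets the centre
  of the inter-outer interval; on each side the *strongest* extremum of the
  appropriate type (deepest minimum on the low-field side, highest maximum
  on the high-field side, with the sign of a genuine lobe) is taken. The
  rules are polarity-agnostic, so mirrored spectra give identical
  splittings.
* **Refinement**: extremum positions and values are refined by a
  least-squares *cubic* over a symmetric window scaled to the line's own
  extremum-pair distance (0.35× for triplet lines, 0.25× for the
  anisotropic anatomy). A plain 3-point parabola is exact on noiseless data
  but becomes noise-dominated on dense grids, where the grid step is far
  smaller than any feature width; the cubic window keeps the noiseless bias
  below half a grid step (the cubic term absorbs the lobe's asymmetry,
  which would otherwise bias a parabola) while averaging noise over tens of
  points.
* **Analyzability**: a spectrum is analyzable only if every required
  extremum exceeds 4× a robust noise estimate (MAD of the detrended edge
  windows). The threshold is configurable; 4 was chosen because on grids of
  ≥ 2048 points pure noise routinely reaches 3.3 σ, so a 3 σ rule would
  classify noise-only records as analyzable. Non-analyzable spectra return
  a flagged row, never an error — mirroring how measured spin-label spectra
  simply drop out of the analysis at unfavourable temperatures.

## Membrane composition

`pigment_concentrations()` implements the standard 80%-acetone equations
(absorbances at 663.2, 664.8 and 470 nm) for chlorophyll a, b, a+b and
total carotenoids, in µg/mL of extract. The coefficient identity
(12.25 − 5.10 = 7.15; 21.50 − 2.79 = 18.71) makes Ca + Cb = Ca+b exact, and
the tests assert it as such. Negative concentrations (blank or turbidity
artefacts) are flagged, never clipped. The default dilution factor of 210
corresponds to 0.01 mL of chloroplast suspension brought to 2.10 mL.

`fatty_acid_profile()` ingests GC-FAME mole-percent tables; saturation is
classified from the parsed `carbons:double_bonds` identifier prefix
(positional tags like "Δ9cis" are ignored for classification), `"<LOD"`
cells contribute zero with an audit flag, and totals outside [95, 105]%
warn. The two fluidity proxies are U/S (total unsaturated over total
saturated) and 18:3/18:2. A packaged table of published barley chloroplast
compositions (wild-type Delisa and the brassinosteroid-deficient 522DK
mutant at three growth temperatures) serves as reference input; recomputed
ratios match the published rows to within ±0.05, the slack expected when
printed ratios were computed from unrounded values.

## Statistics

Replicates are nested: technical replicates are averaged within their
biological replicate first, and means ± SE are reported across biological
replicates. Genotypes are compared per measurement temperature with a
two-sided pooled-variance Student's t-test (`stats::t.test`,
`var.equal = TRUE`), significance at p ≤ α with α = 0.05 — deliberately the
classical Student form, not Welch. **No multiple-testing correction is
applied across measurement temperatures**; each temperature is reported as
its own comparison, and readers of long series should weigh that. Zero
pooled variance with unequal means is reported as p = 0 with a degeneracy
flag. Order-parameter values flagged as outside [0, 1] are excluded from
the statistics by default.

## The synthetic experiment

`run_pipeline()` regenerates a full study: 2 genotypes × 3 growth
temperatures × 2 spin labels, measured at 0–40 °C in 5 °C steps (0–25 °C in
2.5 °C steps for the 5 °C-acclimated group), 2 biological × 2 technical
replicates. The generating trends are fixed package defaults chosen to be
physiologically plausible: S decreases linearly with measurement
temperature from growth-group-specific baselines (0.62/0.64/0.60 for
20/5/27 °C) at 0.006 /°C; τ₂B and τ₂C fall linearly from 7.5·10⁻¹⁰ and
8.5·10⁻¹⁰ s; ΔH₀ falls from 0.22 mT at 0.0015 mT/°C; the mutant is more
ordered and slower than the wild type after growth at 20 and 5 °C (offsets
+0.025/+0.030 on S; factors 1.10/1.25 on τ) and indistinguishable after
27 °C. Biological replicates jitter the generating parameters with 3% CV,
technical replicates with 1.5%; spectra carry noise at SNR 60, and for the
5 °C group's 16-SASL spectra the SNR decays exponentially with measurement
temperature (rate 0.12 /°C) so that high-temperature spectra drop below
the analyzability threshold — emulating the restricted analyzable ranges
seen with cold-acclimated samples.

What the generator does *not* emulate: slow-motion lineshapes between the
two regimes, baseline drifts beyond linear, field-calibration error,
correlated noise, or any genotype effect on pigments and fatty acids (those
enter only through real composition tables). Passing tests therefore
demonstrate that the *analysis chain* is correct and noise-robust under the
stated model, not that the model captures every feature of measured
spectra.

Problem sizes were chosen so the whole suite runs comfortably on one CPU:
4096-point grids for fast-motion accuracy checks, 2048 for anisotropic
ones, 20 parameter sets for the τ sweep, 8 order-parameter targets, and
2000 null simulations for the empirical type-I error.

## Known limitations

* The anisotropic model is phenomenological; extracted A′⊥ carries no
  polarity/overlap correction, matching the raw use of the splitting
  formula.
* τ formulas are motional-narrowing results; outside the fast regime they
  are descriptive indices, not physical correlation times.
* The amplitude identity behind `ground_truth_tau()` requires Lorentzian
  lines; Gaussian simulations have no closed-form τ oracle here.
* Analyzability is a hard threshold; borderline spectra flip with the noise
  realisation, which is faithful to practice but means per-spectrum flags
  (not per-condition guarantees) are what the pipeline reports.
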