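---
title: "Quantifying oxidized nucleotides from Raman, THz-Raman and SERS spectra"
author: "oxiRaman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oxidized nucleotides from Raman, THz-Raman and SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiRaman)
```

## The problem

Reactive oxygen species oxidize guanine at ring position 8, producing
8-oxo-(deoxy)guanosine species (8-oxo-dGTP, 8-oxo-GTP, 8-oxo-dG) that are
the canonical biomarkers of oxidative damage to the nucleotide pool; the
adenine analogue 8-oxo-dATP exists as well. oxiRaman implements a set of
spectroscopic assays that quantify the oxidized fraction
$C^{8\text{-}oxo}$ (in percent) of an oxidized/non-oxidized mixture from:

1. **fingerprint Raman spectra** (900--1700 cm⁻¹), via marker-band
   deconvolution and linear calibration;
2. **low-frequency (THz) Raman spectra** (< 100 cm⁻¹), via an exponential
   shift model of the G-tetrad collective band;
3. **SERS spectra** of nucleosides, via partial least squares regression.

Because no public spectral data accompany these assays, the package ships a
synthetic-spectrum generator that reproduces the statistical structure each
analysis assumes. Every stage is therefore testable end to end, and the
test suite is a parameter-recovery study: the generator hides known truths
and the pipeline must find them.

## Fingerprint marker-band calibration

### Model

A preprocessed mixture spectrum is modeled inside a window as a sum of
Gaussian bands, each parameterized by center $\nu_i$, width $\sigma_i$ and
*integrated area* $A_i$ (amplitude is derived — the calibration consumes
areas, not heights). The oxidation markers of (d)GTP are the 8-oxo bands at
$\nu_A = 1535$ and $\nu_B = 1607$ cm⁻¹; the non-oxidized species
contributes bands at 1485 and 1575 cm⁻¹, and 8-oxo species a further band
at 1445 cm⁻¹. Spectra are first put on a common intensity scale by
dividing by the integrated area of the phosphate-backbone stretch at
$\nu_{PO} = 1123$ cm⁻¹, present in all triphosphates in constant amount.

The normalized marker area then obeys the linear calibration

$$ I_i = m_i \, C^{8\text{-}oxo} + I_i^0, \qquad i \in \{A, B\}, $$

where the intercept $I_i^0$ is the marker intensity observed in the
nominally pure non-oxidized sample — interpreted as an accidental
contamination $C^0$. The $C^0$ correction subtracts the fitted intercept
from every point and refits through the origin, so corrected calibrations
have intercept 0 by construction. The two marker calibrations may be
combined by an inverse-variance-weighted slope average. Inverse prediction
is $C = (I - I^0)/m$ with first-order propagation of the area error, the
slope error and the residual scatter $\sigma_{res}$; the detection limit is
$k\,\sigma_{res}/m$ with the ICH-style $k = 3.3$ (configurable — no
universal criterion exists for band-area calibrations).

### Procedure and numerical choices

* **Baseline**: least-squares polynomial (degree 3 by default; linear in
  the THz range) fit to anchor points and subtracted over the full axis.
  The pipeline derives anchors as the complement of all library band
  regions (center ± 3.5σ); when no windows are supplied, the lowest-decile
  intensity points are used — a heuristic that assumes band-free stretches
  exist across the axis. The fit uses a centered/scaled abscissa for
  conditioning and annihilates any baseline in its own family exactly.
* **Normalization**: integrated area (trapezoidal) in a ±15 cm⁻¹ window
  around 1123 cm⁻¹, not peak height — area is robust to width changes. A
  height alternative was considered and rejected for that reason.
* **Deconvolution**: bounded trust-region least squares (minpack), six
  Gaussians for the 1400--1650 cm⁻¹ (d)GTP protocol: the five assigned
  centers plus one free "background remnant" component initialized
  mid-window with σ = 30 cm⁻¹ — the component count is fixed, no model
  selection. Centers are bounded to ±20 cm⁻¹ of initialization, widths to
  [1, 60] cm⁻¹, areas to ≥ 0; at most 2000 function evaluations, tolerance
  1e-10; hitting the iteration limit sets `converged = FALSE` rather than
  erroring. Standard errors come from $\hat\sigma^2 (J^\top J)^{-1}$ with a
  finite-difference Jacobian (pseudo-inverse fallback when a band collapses
  to zero area and the problem becomes locally singular).
* **Band identity**: inside the pipeline a marker is the Gaussian that was
  *initialized* at its center — in low-C mixtures the marker area is near
  zero and its fitted center is unidentifiable, so re-matching by fitted
  center would fail spuriously. The user-facing `bandArea()` instead does
  nearest-center matching with a 10 cm⁻¹ tolerance and refuses ambiguous or
  absent targets rather than choosing silently; the remnant component can
  be excluded from matching by its assignment.
* **Degenerate inputs**: duplicate wavenumbers, non-finite values,
  all-zero normalization windows, < 3 distinct calibration concentrations
  and zero concentration spread are all hard errors. Negative concentration
  estimates are flagged `belowRange`, never clipped — truncation would bias
  validation statistics.
* The slope SE of a $C^0$-corrected calibration is taken from the
  two-parameter fit: the through-origin refit would ignore the uncertainty
  of the estimated intercept and understate the scatter of the slope (the
  Monte-Carlo suite checks SE calibration against the empirical SD).
* The 8-oxo-dATP assay uses the same machinery on the C5–N7–C8 squeezing
  marker at 620 cm⁻¹ in a 560--680 cm⁻¹ window, without the remnant
  component (mid-window there coincides with the marker itself).

## THz tetrad-shift model

Concentrated guanine nucleotides self-assemble into G-tetrads whose
collective intermolecular modes produce a broad low-frequency band;
oxidation at C8 blocks the Hoogsteen hydrogen bonds and disrupts assembly,
shifting the band by more than 30 cm⁻¹ between the pure species. The
main-band frequency as a function of oxidized fraction is modeled as a
saturating exponential

$$ \nu(C) = \nu_{8oxo} + (\nu_0 - \nu_{8oxo}) \, e^{-C/R}, $$

with $\nu_0$, $\nu_{8oxo}$ the asymptotic frequencies of the non-oxidized
and oxidized species and $R$ (percent) the decay constant; deoxyribo- and
ribonucleotides carry different $R$ values (the sugar modulates long-range
intermolecular interactions). This functional form is the package's
adopted reading of the asymptote semantics; it is stated prominently here
because the literature presents the relation graphically rather than
algebraically. The sensitivity $|d\nu/dC| = |\nu_0 - \nu_{8oxo}|/R \cdot
e^{-C/R}$ is maximal at $C = 0$, which is why the THz observable
outperforms the fingerprint assay at sub-percent oxidized fractions.

Band centers are extracted by `thzMainBand()` — a 1-component Gaussian fit
over 10--200 cm⁻¹, with a second component accepted only if it cuts the
residual RMS by more than 20%, returning the largest-area component — and
never by raw argmax, for noise robustness. `fitExponential()` initializes
$\nu_0$ from the lowest-C point, $\nu_{8oxo}$ from the highest-C point and
$R$ from a log-linearized two-point estimate; equal-frequency input is a
degeneracy error ($R$ unbounded). Inversion is
$C = -R \log\left[(\nu - \nu_{8oxo})/(\nu_0 - \nu_{8oxo})\right]$ with
first-order propagation treating parameter errors as uncorrelated
(correlations from the fit covariance are neglected; at the noise levels
exercised here the interval is dominated by the frequency error).

## SERS quantification by PLS

SERS spectra of dG/8-oxo-dG mixtures on silver colloid are too congested
for band-by-band deconvolution, so the oxidized fraction is regressed
directly on the spectrum: unit-vector normalization over 400--1800 cm⁻¹
(a window that contains the main nucleoside bands and excludes the colloid
band near 240 cm⁻¹), mean centering, and PLS1 with 3 latent components by
NIPALS with deflation. The implementation is deterministic — the first
weight vector is the response-covariance direction — and authored in-repo;
an established PLS library is used only as an equivalence oracle in the
tests (agreement to better than 6 significant digits on random matrices).
No variance scaling is applied, since all channels share units. Model
selection of the component count is out of scope; 3 components are the
stated protocol. Validation is leave-one-out cross-validation (the
smallest-variance choice at these sample sizes), reporting the
predicted-vs-actual table and RMSECV. Out-of-range predictions are flagged,
not clipped.

## What the synthetic generator emulates — and what it does not

The generator produces spectra as sums of Gaussian bands at the assigned
centers on a smooth polynomial baseline with additive homoscedastic
Gaussian noise (SD expressed as a fraction of the maximum band signal):

* **Fingerprint** axis 300--1800 cm⁻¹ at 0.5 cm⁻¹ and **THz** axis
  10--200 cm⁻¹ at 0.25 cm⁻¹ — finer than a real 3 cm⁻¹ instrument
  resolution, so fitting error is grid-independent. Band widths are not
  experimentally documented; σ = 8 cm⁻¹ (fingerprint) and σ = 25 cm⁻¹
  (THz broad band) are free generator parameters, and all library areas
  are stand-ins, clearly so.
* **Mixtures** are exactly linear: $(1-C/100)\,S_A + (C/100)\,S_B$, so
  marker areas are affine in $C$ before noise; an optional `c0Pct`
  simulates the accidental contamination the $C^0$ correction removes.
  The default fraction grid is 0--16% (the biologically occurring range
  for guanine oxidation), 3 replicates.
* The phosphate band area is scaled so its integral over the default
  ±15 cm⁻¹ normalization window is exactly 1; marker areas 0.8 (A) and
  0.9 (B) then make the true calibration slopes 0.008 and 0.009 normalized
  intensity per percent — the values the recovery suite targets.
* **THz series** place one broad Gaussian at $\nu(C)$ from a
  `TetradShiftModel`; deoxy defaults $(\nu_0, \nu_{8oxo}, R) = (95, 60, 6)$
  and ribo $(92, 61, 3)$ are placeholders consistent with a > 30 cm⁻¹
  pure-species shift and distinct decay rates. Coverage and
  below-zero-truncation checks use center ± 2σ (a 3σ rule would reject the
  legitimate broad 60 cm⁻¹ band on a 10--200 cm⁻¹ axis).
* **SERS** spectra are $g\,[(1-C/100)\,S_{dG} + (C/100)\,S_{8oxo} +
  S_{colloid} + B] + \varepsilon$ with a lognormal per-spectrum gain $g$
  (sdlog 0.2 by default) modeling enhancement and collection-efficiency
  variability. The gain multiplies the whole measured emission — that is
  both the physical model for collection-efficiency fluctuations and the
  reason unit-vector normalization removes it exactly; detector noise is
  added after the gain.
* Heteroscedastic (shot-noise-like) noise, cosmic spikes, instrument
  response functions, Lorentzian/Voigt line shapes and wavenumber
  miscalibration are **not** simulated. Passing tests therefore demonstrate
  correctness of the algorithms under the model's own assumptions, not
  performance on real instrument data; in particular the recovered
  detection limits describe the synthetic noise level, nothing more.

## Problem sizes used in the validation suite

The recovery studies run at deliberately modest sizes, chosen so the whole
suite doubles as a quick regression check: the calibration study uses 21
spectra (7 fractions × 3 replicates) at 1% noise; Monte-Carlo suites use
100--200 draws; PLS validation uses 11 mixtures spanning 0--100%. At these
sizes the slope recovery lands within the ±0.001 uncertainty quoted for
the real assay, and RMSECV of the SERS regression is well below 2%.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
man <- generateMixtureSeries(fractions = c(0, 1, 2, 4, 8, 12, 16),
                             replicates = 3, noiseSD = 0.01, seed = 42)
cal <- markerCalibration(man)
cal$curves[["1535"]]
avg <- averageCalibration(cal$curves[["1535"]], cal$curves[["1607"]])
predictConcentration(avg, 0.07)
detectionLimit(avg)
```

## Known limitations

* The six-Gaussian protocol's free remnant component trades area with the
  1535 cm⁻¹ marker under noise at the single-spectrum level (a ~1σ effect
  at 1% noise); calibration across a series averages this out, but
  single-spectrum marker areas should be read with their standard errors.
* Inverse-prediction intervals use first-order propagation with normal
  quantiles; at very few calibration points a t-quantile would be more
  faithful.
* No re-gridding: spectra entering PLS must share a wavenumber grid
  exactly. This is intentional (silent resampling hides acquisition
  mismatches) but means mixed-instrument datasets need explicit
  interpolation by the user.
* Vendor binary formats (SPC, WDF, JCAMP-DX) are not read; the two-column
  text dialect with `# key: value` headers is the package's interchange
  format.
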