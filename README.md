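# oxiRaman

Quantification of oxidized purine nucleotides — 8-oxo-dGTP in dGTP,
8-oxo-GTP in GTP, 8-oxo-dATP in dATP, 8-oxo-dG in dG — from Raman,
low-frequency (THz) Raman and surface-enhanced Raman (SERS) spectra. It is
aimed at analytical spectroscopists and chemometricians who need a tested,
scriptable version of the three assays, plus a synthetic-spectrum generator
that makes every stage verifiable without instrument data.

## What it computes

**Fingerprint marker calibration.** Mixture spectra are
baseline-subtracted, normalized to the integrated area of the phosphate
stretch at ν<sub>PO</sub> = 1123 cm⁻¹, and deconvolved with six bounded
Gaussians in 1400–1650 cm⁻¹. The normalized areas *I* of the 8-oxo marker
bands at ν<sub>A</sub> = 1535 and ν<sub>B</sub> = 1607 cm⁻¹ follow

&nbsp;&nbsp;&nbsp;&nbsp;*I<sub>i</sub>* = *m<sub>i</sub>* · *C*<sup>8-oxo</sup> + *I<sub>i</sub>*⁰ ,  i ∈ {A, B},

where the intercept measures an accidental oxidized contamination *C*⁰ of
the pure sample; after its subtraction the calibration passes through the
origin by construction. Inversion gives *C* = (*I* − *I*⁰)/*m* with
propagated uncertainty; the detection limit is *k*·σ<sub>res</sub>/*m*
(k = 3.3). The same machinery handles the 8-oxo-dATP marker at 620 cm⁻¹.

**THz tetrad-shift model.** The broad G-tetrad collective band shifts by
over 30 cm⁻¹ upon oxidation; its center follows
ν(*C*) = ν<sub>8-oxo</sub> + (ν₀ − ν<sub>8-oxo</sub>)·e<sup>−C/R</sup>,
whose maximal slope at *C* = 0 gives sub-percent sensitivity.

**SERS + PLS.** Unit-vector-normalized SERS spectra (400–1800 cm⁻¹) are
regressed on the oxidized fraction with 3-component NIPALS PLS1 and
validated by leave-one-out cross-validation.

## Worked example

```r
library(oxiRaman)

man <- generateMixtureSeries(fractions = c(0, 1, 2, 4, 8, 12, 16),
                             replicates = 3, noiseSD = 0.01, seed = 42)
cal <- markerCalibration(man)
cal$curves[["1535"]]
#> CalibrationCurve [band 1535]: I = 0.0079852 * C + 0
#>   slope SE 0.000126 | sigma_res 0.00556 | n = 21 | C in [0, 16]% | C0-corrected: TRUE
cal$curves[["1607"]]
#> CalibrationCurve [band 1607]: I = 0.0089549 * C + 0
#>   slope SE 9.66e-05 | sigma_res 0.00269 | n = 21 | C in [0, 16]% | C0-corrected: TRUE
```

The generator hid true slopes of 0.008 and 0.009 normalized intensity per
percent; the full pipeline recovers 0.00799 and 0.00895 from 21 noisy
spectra. Averaging the two markers and inverting for an unknown:

```r
avg <- averageCalibration(cal$curves[["1535"]], cal$curves[["1607"]])
predictConcentration(avg, 0.07)
#> ConcentrationEstimate: C = 8.144 +/- 0.513 % (curve averaged)
detectionLimit(avg)   # k * sigma_res / m, k = 3.3
#> [1] 1.68
```

i.e. a measured normalized marker area of 0.07 corresponds to 8.1 ± 0.5%
oxidized content, and this calibration resolves oxidized fractions down to
about 1.7% at the simulated noise level. The THz route recovers its model
exactly from noiseless band centers:

```r
ser <- generateThzSeries(fractions = c(0, 1, 2, 4, 8, 16))
fitThzSeries(ser$spectra, ser$fractions)$model
#> TetradShiftModel: nu(C) = 60 + (95 - 60) exp(-C/6)
```

and the SERS/PLS route cross-validates to RMSECV = 0.16% over mixtures
spanning 0–100%:

```r
d <- generateSersDataset(seed = 42)
crossValidatePLS(d$spectra, d$fractions)$rmsecv
#> [1] 0.1612309
```

See `vignettes/oxiRaman-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

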