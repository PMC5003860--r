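---
title: "Quantitative wide-field optical mapping: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative wide-field optical mapping: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfomtools)
```

# The measurement problem

Wide-field optical mapping (WFOM) images the exposed cortex with a camera
while strobed LEDs illuminate it at several wavelengths. Two kinds of signal
are interleaved on the same sensor: diffuse reflectance, which carries
haemoglobin absorption information, and fluorescence (e.g. GCaMP), which
carries neural activity but is filtered through the same time-varying
absorption. `wfomtools` implements the computational chain that turns these
raw counts into physical quantities, and a synthetic phantom that makes
every inverse step testable against known truth.

# Spectroscopic model

## Modified Beer-Lambert conversion

In a clear absorber, transmitted intensity follows `I = I0 exp(-mua x)`.
Cortex scatters strongly, which both lengthens photon paths and makes the
detected geometry uncertain. The working approximation is the modified
Beer-Lambert law: attenuation `exp(-mua X + G)` with an *effective mean
pathlength* `X = DPF * x` and a geometry term `G`. Neither the illumination
distribution nor `G` is knowable per pixel, but both are static, so they
cancel in the ratio `I(t) / I(t0)` against a baseline epoch. That is why the
package's reflectance processing is strictly ratiometric
(`reflectance_ratio()`), and why the fractional change dR/R is the quantity
worth comparing across laboratories: it is independent of pathlength and
extinction assumptions.

From the ratio, `delta_mua()` estimates the change in the absorption
coefficient, `dmua = -ln(I(t)/I(t0)) / X(lambda)`, and haemoglobin changes
follow from the two-chromophore decomposition

```
dmua(lambda_i) = xi_HbO(lambda_i) dHbO + xi_HbR(lambda_i) dHbR
```

solved per pixel by `solve_two_wavelengths()` (2x2) or
`solve_multiwavelength()` (least squares at 3+ wavelengths, residual
reported). Changes in other chromophores (cytochrome oxidase, water,
lipids) are neglected: they contribute to *baseline* absorption but cancel
in the differential unless their concentrations change, which in the
450-700 nm window is a small effect. Absolute (non-differential)
spectroscopy is out of scope.

## The unit trap

Extinction compilations are decadic (base-10) and per cm; the attenuation
model is natural-exponent and per mm. Mixing these silently is the most
common quantitative error in this analysis. The package's rule: extinction
tables are stored decadic in cm^-1 M^-1 exactly as compiled, every internal
absorption coefficient is natural-log in mm^-1, and the conversion factor
`ln(10)/10` is applied in exactly one place (`xi_natural_mm()`).
`xi_matrix()` returns solver-ready matrices on the natural scale.

## Extinction fixture

The packaged table (`inst/extdata/hb_extinction_synthetic.csv`) is a
synthetic reconstruction of the standard HbO2/Hb molar extinction
compilation: literature anchor values on a ~5-10 nm grid, linearly
interpolated to 1 nm over 450-700 nm. It reproduces the two
quantitatively load-bearing features: the green isosbestic crossing near
530 nm (`find_isosbestic()` locates it on the grid) and the baseline
absorption values implied by standard cortical blood content. With 2 mM
haemoglobin in whole blood, 3% blood volume and 75% saturation
(`blood_assumptions()` defaults), `baseline_mua()` gives 0.55 mm^-1 at
530 nm and 0.024 mm^-1 at 630 nm. Between anchors the table is linear;
fine spectral structure away from the anchors is smoothed, which matters
only for narrow bands centred between anchors. LED bands of finite width
are handled by `band_effective_extinction()`, which integrates the
extinction under a unit-area emission spectrum (measured, Gaussian,
boxcar, or delta).

## Isosbestic channel

At an isosbestic wavelength the two extinctions are equal, so the
reflectance ratio is blind to the HbO/HbR split and reports total
haemoglobin only: `isosbestic_hbt()` returns both the calibrated dHbT and
the raw `-ln(ratio)`, which is proportional to dHbT with *no* pathlength or
extinction input at all. Because a real LED band has finite width, a band
centred on the isosbestic point retains slight oxygenation sensitivity; on
the packaged table the residual saturation dependence at the empirical
isosbestic point is below 5% over the full 0-100% saturation range.

## Pairwise consistency

With three wavelengths, `pairwise_consistency()` converts every pair
separately. If the conversion model holds — a shared chromophore mixture
seen through correct pathlengths — all three solutions agree; a
wavelength-dependent pathlength error breaks the agreement. The discrepancy
metric is the maximum over pairs of the RMS deviation from the pair-mean
solution, relative to the RMS of the mean solution, with a default
tolerance of 5%. The check is most sensitive to errors on the
high-extinction (green) channel; an error confined to the red channel
moves the solution less because red carries an order of magnitude less
absorption signal.

# Monte Carlo pathlength and sensitivity model

`simulate_reflectance()` runs photon transport in a homogeneous
semi-infinite medium: uniform planar unidirectional illumination
(equivalently, photons launched at a point with exit positions taken
relative to the detection pixel), Henyey-Greenstein scattering, continuous
absorption weighting `exp(-mua s)` along each segment, Russian roulette
below weight 1e-4 with survival 0.1, a 10 mm depth cutoff, and detection
within a low-NA cone (default NA 0.2) at the surface. A Fresnel boundary
(n = 1.37 vs 1.0) reflects photons internally at the exit surface by
default; `fresnel = FALSE` gives an index-matched boundary. Layered media,
voxelised vasculature, polarisation and speckle are out of scope.

Design choices worth stating:

* **Continuous absorption weighting** rather than terminal absorption
  sampling: the same photon set then supports absorption-perturbation
  identities. `reweighted_reflectance()` recomputes `R(mua + d)` from the
  stored detected pathlengths, and `-(ln R(mua+d) - ln R(mua))/d`
  reproduces the mean detected pathlength — the adjoint identity that also
  fixes the normalisation of the sensitivity map. The suite checks this at
  1e6 photons (agreement well under 5%; the identity is exact in the
  d -> 0 limit by construction).
* **Weight ledger**: detected + escaped-outside-NA + transmitted-below-
  cutoff + absorbed + roulette losses - roulette gains equals the launched
  weight to ~1e-13 relative; asserted at 1e-6 in tests.
* **Binning**: z positive downward, x lateral signed distance from the
  detection pixel, half-open bins; path segments are subdivided below half
  the bin size before deposition so the (x, z) map is not quantised by the
  scattering step length. Deposits outside the grid accumulate in an
  overflow term so the adjoint identity stays exact.
* **Determinism**: all randomness comes from R's RNG seeded once per run;
  a fixed seed reproduces results bit-for-bit.

The absolute pathlength scale depends strongly on the boundary condition,
NA and refractive index — published rodent-cortex values span a factor of
about 3 for this reason. The packaged pathlength table
(`inst/extdata/pathlength_mc_synthetic.csv`) was generated by
`pathlength_table()` itself (2e5 photons per wavelength, 450-700 nm in
10 nm steps, seed 20260924) at literature optical properties: absorption
from the blood-content assumptions above, scattering and anisotropy
interpolated between 21/21/24 mm^-1 and 0.80/0.82/0.87 at 488/530/630 nm.
Its *shape* is the physically meaningful part: pathlength is inversely
driven by absorption (minima at the haemoglobin peaks, ~7-fold longer at
630 nm than 530 nm, deeper mean sensing depth in the red); users converting
real data should calibrate the absolute scale for their own geometry, or
regenerate the table with their NA and boundary settings. The scattering
spectrum helper `scatter_power_law()` implements the
`(lambda/lambda_ref)^-b` dependence with b typically 1.3-2 in brain.

`simulate_fluorescence()` handles the two-leg epifluorescence geometry:
excitation transport accumulates a depth-resolved fluence; emission photons
launch isotropically from depths sampled proportional to fluence times the
fluorophore density profile and are detected within the NA cone. It
reports mean excitation- and emission-leg pathlengths and the detected
fraction per origin depth, which is strongly superficially weighted for
uniform labelling. The excitation leg is fluence-weighted (every passage
through a depth bin is a conversion opportunity), so in a *non-absorbing*
medium even a surface-confined fluorophore has a finite mean leg from
multiply-scattered passages; with realistic absorption the short first
passages dominate and surface legs are sub-millimetre. Tests assert the
orderings (legs grow with depth, detection falls with depth) rather than a
zero limit for this reason.

# Fluorescence cross-talk corrections

After dark subtraction — mandatory, because the static gain field S(r) can
only cancel from the ratio once the additive dark level D(r) (up to ~100
counts) is removed; `dark_subtract_ratio()` refuses a missing dark rather
than assuming zero — the measured fluorescence ratio is

```
F(t)/F(t0) = [c_f(t)/c_f(t0)] * exp(-[dmua_ex X_ex + dmua_em X_em])
```

i.e. the activity ratio times a *multiplicative* haemodynamic attenuation
accumulated along the excitation and emission legs. Because the
contamination is multiplicative, a brighter fluorophore changes nothing:
scaling the brightness cancels in the ratio, a property the suite asserts
literally. Three corrections are provided:

1. **Single-wavelength** (`correct_single_wavelength()`): divide by a
   co-registered reflectance ratio near the emission band. Exact when the
   absorption change is the same at both bands and the reflectance
   pathlength equals the sum of the two legs; otherwise it leaves a
   bounded residual (larger than the Ex-Em method's on the same phantom).
2. **Excitation-emission** (`correct_ex_em()`): invert two reflectance
   wavelengths to (dHbO, dHbR), reconstruct dmua at the actual excitation
   and emission bands through the extinction table, and multiply by
   `exp(dmua_ex X_est_ex + dmua_em X_est_em)`. The default effective
   pathlengths (0.56 and 0.57 mm) are values that minimise vessel
   artefacts in Thy1-GCaMP mouse preparations; they are configuration, not
   constants, and should be re-estimated for other indicators or species.
   (Reported compilations sometimes print these in mm^-1; the exponent is
   dimensionless only if they are lengths, and the package treats them as
   mm.)
3. **Log-space PCA** (`correct_pca_log()`): when no reflectance was
   recorded, the multiplicative contamination is additive in the log, so a
   principal component of `ln(ratio)` (centred per pixel over time) can be
   subtracted and the result exponentiated. The haemodynamic component is
   selected by temporal correlation against a reference trace when one is
   supplied; without a reference an explicit index is required — component
   order is not stable, so the package never guesses. If no component
   passes the correlation threshold the movie is returned unchanged.

Each method is exact on a phantom built under its own assumptions, and that
is precisely what the tests assert. On the shared phantom — where the
contamination is *not* rank-1 because several vascular compartments
contribute — PCA removes only the dominant component and agrees with the
Ex-Em trace to about 0.03 dF/F RMS; the cross-method test allows 0.05.
This is the expected failure mode of blind-source removal on
multi-compartment data, not a defect of either implementation. Recommended
pre-processing (trial averaging, 3-5 Hz low-pass via `lowpass_time()`)
reduces physiological noise before regression or PCA.

`fit_gamma_kernel()` supports validation against electrophysiology: it fits
fluorescence as spiking activity convolved with a gamma kernel (amplitude
profiled out linearly, shape and scale optimised in log space). The kernel
is discretised by per-bin integrated mass so the narrow-kernel limit
degenerates cleanly to a scaled copy of the input; a zero spike train is
flagged as unidentifiable rather than fitted.

# Compartment unmixing

Vascular compartments have distinct haemodynamic signatures — arteries
dilate (dHbT up, little dHbR change), veins wash out deoxyhaemoglobin
(strong dHbR decrease, minimal dHbT) — and `build_basis()` extracts them as
mean (dHbO, dHbR, dHbT) traces over user-selected seed regions,
concatenated per compartment. `unmix_nnls()` then solves a non-negative
least-squares problem per pixel (Lawson-Hanson, via `pracma::lsqnonneg`),
yielding coefficient maps and a residual map. Choices:

* The dHbT block is linearly dependent on the other two; it is kept by
  default for fidelity to the concatenated-signature convention and can be
  dropped (`blocks = c("hbo", "hbr")`). Keeping it implicitly doubles the
  weight of the volume signal in the fit.
* Basis rows are not normalised by default, so coefficients read as
  "concentration of each signature"; `normalize = TRUE` rescales for
  display. Collinear rows produce a warning (coefficients not unique), not
  an error.
* Seeds are user-supplied; automatic vessel segmentation is out of scope.

The suite verifies NNLS against an exhaustive active-set oracle, checks
that expanding a 3-compartment basis to 5 never increases any pixel's
residual, and that anti-correlated traces are clamped to zero coefficients.
`render_merge()` produces the colour composite with recorded per-map
scaling.

# The synthetic phantom

`make_scene()` builds the ground-truth scene every inverse operation is
tested against: binary artery/vein (optionally arteriole/venule) bands over
a Gaussian-blurred capillary background (the blur emulates how deep
capillary beds appear as diffuse background under sharp surface vessels),
a smooth static gain field, a camera dark level (default 100 counts), and
per-compartment haemoglobin time courses shaped as stimulus-convolved gamma
responses. Each compartment has its own transit delay (arterial side leads,
venous side lags) — both physiologically expected and what makes the
concatenated signatures linearly independent, the premise of seeded
unmixing. Peak amplitudes are ~1-12 uM, typical of stimulus-evoked cortical
responses. The fluorophore activity ratio rises quickly at stimulus onset,
adapts toward a sustained plateau (25% of peak by default) and decays at
offset, while the hyperaemia builds later; with the default 8% peak dF/F
and ~10 uM HbT response, the uncorrected fluorescence trace dips below
baseline at peak hyperaemia while the true activity never does — the
canonical cross-talk signature the corrections must undo.

`forward_reflectance()` and `forward_fluorescence()` run the attenuation
models forwards (effective pathlengths, not 3-D transport inside the
phantom — deliberately matched to the inverse models under test). Noise is
optional scaled Poisson on pre-dark counts plus Gaussian read noise; the
default baseline of 1e4 counts corresponds to 40 dB per-frame amplitude
SNR. All randomness derives from the phantom seed (channel streams are
offset deterministically), so reruns are bit-identical.

What passing these tests shows — and does not. The phantom validates the
algebra and the statistical behaviour of every inverse step under its own
forward model. It does not emulate 3-D partial-volume mixing,
wavelength-dependent sampling-volume mismatch, motion, or pulsation; on
real data those enter as model error that the pairwise-consistency check
and the residual maps are designed to surface, not eliminate.

# Numerical choices and problem sizes

* Extinction matrices with condition number above 1e8 are rejected as
  singular: beyond that the two-wavelength inversion only amplifies noise.
* Invalid pixels (baseline at or below dark, non-positive ratios)
  propagate as masks (NA plus a validity matrix), never silently.
* Baselines are means over a user-set frame window, not single frames, to
  suppress shot noise; the window length is configuration (no universal
  default exists).
* Nonlinear pathlength re-estimation from inferred absorption changes is
  deliberately not iterated; it risks divergence for little benefit at
  these signal levels.
* Default test problem sizes: 20-30 px phantoms with 40-120 frames, 1e4-1e6
  Monte Carlo photons depending on the identity under test. These sizes
  were chosen so the full validation cycle stays interactive while keeping
  every statistical assertion comfortably inside its tolerance at the
  fixed seeds used.
* I/O: counts as 16-bit multipage TIFF; derived float movies as 32-bit
  TIFF with an affine scale sidecar (`.scale.json`); tables and QC reports
  as CSV/JSON. All writes are atomic (temp file + rename), so an
  interrupted run never leaves a truncated file that parses. Pixel
  conventions: origin top-left, row-major, 1-based in R, 0-based in JSON
  ROI files.

# Known limitations

* Both packaged fixtures are synthetic stand-ins (reconstructed extinction
  anchors; self-generated pathlengths); their absolute scales carry more
  uncertainty than their shapes.
* The Monte Carlo medium is homogeneous and semi-infinite; surface vessels
  violate homogeneity exactly where sensitivity is highest.
* The phantom's attenuation is depth-integrated; it cannot expose errors
  arising from genuine 3-D heterogeneity of the sampling volume.
* PCA correction degrades on long or multi-event recordings where
  components mix; it is intended for short, single-event epochs.
* `fit_gamma_kernel()` assumes a single stationary kernel; indicator
  nonlinearity and saturation are not modelled.
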