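---
title: "From wing-scale nanostructure to perceived colour: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wing-scale nanostructure to perceived colour: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliris)
```

## The problem

Iridescent blue-green colour in *Heliconius* butterflies is structural: the
longitudinal ridges of the wing scales carry stacked cuticle lamellae that
act as a multilayer reflector. Three physical descriptors organise the
variation between taxa — the spacing between ridges (how densely the
reflectors are packed), the layer period within a ridge (which wavelength is
reflected), and the flatness of the lamellae (how much of the ridge reflects
coherently). `heliris` implements the full analysis chain that connects
these descriptors to the colour a bird or a butterfly actually perceives:
reflectance spectrometry processing, multilayer optics, ridge-spacing
estimation from small-angle X-ray scattering (SAXS) and atomic-force
microscopy (AFM), and receptor-noise-limited visual modelling, together
with seeded synthetic-data generators that emulate each instrument so the
whole pipeline is testable without instrument files.

## Reflectance spectra

Spectra are two-column tables (wavelength in nm, reflectance in % of a
diffuse white standard), one file per incidence angle. Processing follows
the standard spectrometry chain:

1. **Resampling** to a common 1 nm grid (linear interpolation, no
   extrapolation). The acquisition grid of a typical CCD spectrometer is
   irregular and denser than 1 nm, so nothing is lost; 1 nm is also the
   integration step of the visual models.
2. **Smoothing** by degree-2 local regression (`stats::loess`, tricube
   weights) with `span` the fraction of points in the window; the default
   `span = 0.3` matches the processing the pipeline emulates. Negative
   smoothed values are clamped to zero *after* smoothing — the
   fix-negatives-last convention — because clamping first would bias the
   local fits near zero.
3. **Min-zero normalisation**: the minimum over the working range is
   subtracted so each spectrum's baseline is exactly zero. The operation is
   idempotent.
4. **Averaging** repeated measurements pointwise where an individual was
   measured more than once.

Summary descriptors are computed on the working range **300–700 nm**, the
shared bird/butterfly visible range: peak wavelength (argmax), FWHM (linear
interpolation of the two half-maximum crossings flanking the peak) and
maximum reflectance. Two boundary conventions matter in practice:

* a spectrum that is still rising at 700 nm (the non-iridescent phenotype)
  is reported with its peak at the window edge and flagged
  `peak_at_boundary`; its FWHM is reported missing rather than
  extrapolated, since the flanking crossing does not exist inside the
  window;
* the angle of maximum reflectance is the angle whose spectrum attains the
  global maximum; exact ties go to the smaller absolute angle — a pure
  reproducibility convention with no physical claim. Quadratic refinement
  over the three bracketing angles is available but off by default, so the
  reported angle is always one that was actually measured.

## Multilayer optics

A ridge is modelled as a periodic stack: an ordered unit cell of
non-absorbing layers (refractive index `n`, thickness `d` in nm) repeated
`repeats` times between ambient air and a chitin substrate. The measured
unit cell for the brightest iridescent taxon is 119 nm of air over 85 nm of
chitin (`n = 1.56`), with two repeats — cross-sections show approximately
two regular periodic protrusions per ridge — available as
`sara_ridge_stack()`.

Two predictions are implemented:

* the **first-order constructive-interference wavelength**
  $\lambda_1 = 2\sum_i d_i\sqrt{n_i^2-\sin^2\theta}$, which at normal
  incidence is $2\sum_i n_i d_i$ — for the measured cell
  $2(1.0\cdot119 + 1.56\cdot85) = 503.2$ nm;
* the exact **transfer-matrix reflectance** of the finite stack
  (characteristic 2×2 matrices per layer, s and p polarization,
  unpolarized = mean), vectorized over wavelength.

The thickness-weighted mean index of the measured cell is
$(1.0\cdot119+1.56\cdot85)/204 = 1.2327$. The source measurements quote a
slightly lower rounded effective index; we keep the plain thickness-weighted
mean rather than reverse-engineering the rounding, since the resulting
first-order wavelength is inside the quoted uncertainty band either way.

The model is deliberately lossless: melanin absorption under the reflector
affects brightness but not the interference condition the package is used
to check, so absorption is out of scope. Indices are wavelength-independent
(no dispersion). The transfer-matrix engine is verified in the test suite
against two closed forms — the Fresnel single-interface reflectance and the
quarter-wave-stack formula — to 1e-10, plus reciprocity and the
zero-contrast null.

## Ridge spacing

**SAXS route.** A detector pixel at distance $r$ from the beam centre maps
to momentum transfer $q = (4\pi/\lambda)\sin(\tfrac12\arctan(r/D))$; the
synchrotron geometry (0.1 nm X-rays, $D$ = 30.98 m, here with 0.05 mm
pixels on a 256 px detector) puts the ridge-spacing ring (spacings
0.7–1.3 µm, $q_0 = 2\pi/d$) comfortably inside the detector. Radial
integration averages unmasked counts in 300 equal q bins. The spacing
estimator fits a single power law $I = Aq^{-m}$ on the flanks outside the
search window (standard for small-angle form-factor decay), subtracts it,
requires the residual maximum inside the window to be a genuine interior
peak standing at least five residual standard deviations above the flank
scatter (otherwise a no-peak error), refines the position with a 3-point
parabolic fit, and returns $d = 2\pi/q_{\text{peak}}$. The default window
$2\pi/1500 \ldots 2\pi/500\ \text{nm}^{-1}$ brackets all observed spacings
and is user-overridable.

**AFM route.** A height map is de-trended by its best-fit plane, Hann
windowed, and its 2-D FFT power spectrum azimuthally integrated to power
versus spatial frequency, which makes the estimate invariant to the
in-plane ridge orientation. The dominant non-DC bin must stand an order of
magnitude above the median annulus power (featureless maps raise a no-peak
error). Because the windowed ridge line spreads symmetrically over a few
DFT bins, the final frequency is the power-weighted centroid over the
annulus within ±2.5 bins of the dominant bin, which removes the half-bin
quantisation of the plain binned maximum; the suite shows both estimators
recover every observed spacing value to well under 1 % and agree with each
other within 2 % on paired synthetic specimens.

## Visual modelling

Receptor sensitivities are built from the standard A1 visual-pigment
template (Govardovskii-type alpha band plus beta band) given only each
receptor's peak wavelength, normalised to unit peak — the usual practice
when full recorded curves are not tabulated. Five receiver models are
bundled (`builtin_visual_systems()`):

| system | receptors (λmax, nm) | Weber w | abundances (ref L = 1) |
|---|---|---|---|
| avian VS | 416, 478, 542, 607 | 0.06 | 0.25, 0.5, 1, 1 |
| *Heliconius* I | 355, 390, 470, 555 | 0.05 | 0.09, 0.07, 0.17, 1 |
| *Heliconius* II | 390, 470, 555 | 0.05 | 0.13, 0.2, 1 |
| *Heliconius* III | 355, 390, 470, 555 | 0.05 | 0.09, 0.13, 0.2, 1 |
| *Heliconius* IV | 355, 470, 555 | 0.05 | 0.07, 0.26, 1 |

Types III and IV abundances can be re-derived with `derive_abundances()`
from ommatidial-type fractions times within-type receptor proportions. The
avian system applies a smooth short-wavelength cut-on approximating
passerine ocular-media transmission (toggleable; it has little effect);
avian oil-droplet filtering is deliberately omitted, as it is not part of
the receptor description the pipeline uses. Illuminants: CIE D65
(tabulated at 10 nm, interpolated), and a "forestshade" constructed as D65
times a smooth synthetic canopy transmission — UV-poor (logistic cut-on
around 400 nm) and green-peaked (Gaussian at 555 nm over a 15 % broadband
floor). It reproduces the qualitative character of canopy shade
(green-shifted, UV-poor); absolute parity with any published forest-shade
tabulation is not claimed, which is one reason absolute JND values on real
wings are not reproduction targets here.

Quantum catches are trapezoid integrals of reflectance × sensitivity ×
illuminant × ocular transmission on the 1 nm grid; the von Kries transform
divides by the catch of a perfect white reflector under the same
illuminant, so the adapting white has unit catch in every receptor.
Colour coordinates use von-Kries relative catches: tetrachromats in the
standard tetrahedral colour space (achromatic centre at the origin,
pure-receptor vertices at distance 0.75), trichromats in a unit-edge
Maxwell triangle.

Discriminability follows the receptor-noise-limited model with log-coded
signals $\Delta f_i = \ln(Q_{a,i}/Q_{b,i})$ and channel noise
$e_i = w\sqrt{\eta_L/\eta_i}$, with L the reference receptor ($\eta_L = 1$,
so $e_L = w$). The closed trichromat/tetrachromat forms are implemented
directly; the suite verifies them to 1e-10 against the equivalent
noise-weighted projection form $\min_c \sum_i (\Delta f_i - c)^2/e_i^2$,
which is an independent derivation of the same model. Achromatic
discriminability uses the L receptor only: $|\Delta f_L|/w$, so one Weber
step is one JND. Chromatic JND is invariant to scaling either spectrum
(intensity independence), zero exactly for proportional catches, and
symmetric.

Because neither the wing spectra nor the recorded *Heliconius* sensitivity
curves are deposited, absolute JND values from the original co-mimic
comparisons are not reproduction targets. The acceptance suite instead
asserts the model's defining properties, plus a fixed synthetic co-mimic
fixture — two 4-individual groups generated from ridge multilayers whose
period differs by 8 nm, with seeded 0.5 % spectral noise — whose
cross-system ordering of mean chromatic JND is frozen as a regression
value for these fixtures, not as a biological claim.

## Statistics

Per-taxon tables aggregate per-individual descriptors to mean ± sample
s.d. (n − 1; single individuals get a missing s.d.). The planned
association test is a Pearson correlation between mean SAXS ridge spacing
and mean maximum reflectance across taxa, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ d.f.; on the transcribed study table
(7 taxa with SAXS values; the single-individual taxon has none) this gives
r = −0.829, p = 0.021, and the t-based p agrees with the exhaustive
5040-permutation p-value within 0.01. Clade-wise ordinary-least-squares
slopes of reflectance on spacing use a configurable taxon→clade map
(defaults: *erato* group = *e. demophoon*, *e. cyrbia*, *sara*,
*eleuchia*; *melpomene* group = *cydno*, *m. cythera*, *m. rosina*); the
slope contrast is reported descriptively, with no formal slope-difference
test and no multiple-testing correction (a single planned test).

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a mandatory seed
(the global RNG stream is saved and restored). Defaults are set to the
study conditions: spectral amplitudes and peak positions in the observed
1–35 % / 350–500 nm ranges, FWHM 70–95 nm, spectrometer noise 0.5 %
(Gaussian), measurement angles every 2–5°, SAXS in the synchrotron
geometry with Poisson counting noise (photon statistics) and a central
beam-stop mask, AFM as 10 µm/512 px scans with 5 nm Gaussian roughness and
60 nm ridge amplitude. The angular envelope of a measurement series is
Gaussian (centre ≈ the measured angles of maximum, width 15°).

The generators reproduce the *signal structure* the estimators rely on —
angle-dependent interference peaks, a Debye–Scherrer-type ring on a
power-law background, periodic ridges with curved/sawtooth variants — but
not everything about real wings: no speckle or scale-to-scale
heterogeneity, no multi-order SAXS peaks or anisotropic arcs, no AFM tip
convolution or scan-line artefacts, and spectral noise is white rather
than wavelength-correlated. Passing round-trip tests therefore shows the
estimators are correct and well-conditioned at realistic signal-to-noise,
not that every instrument artefact is handled.

Problem sizes used throughout the tests — 256 px detectors, 512 px height
maps, 300 q bins, 1 nm spectral grids — are the package's defaults and
match the information content of the emulated instruments (the ring and
ridge frequencies sit far from both DC and Nyquist).

## Numerical choices and degenerate inputs

* Peak refinement (SAXS q, angle series) is 3-point parabolic; it falls
  back to the grid maximum when the bracket is degenerate.
* FWHM crossings use linear interpolation between samples; truncated
  crossings yield a missing FWHM with a flag rather than a guess.
* `ridge_spacing_from_profile` demands an interior, significant residual
  maximum; monotone or background-only profiles raise a no-peak error, as
  do featureless height maps.
* Ties in `angle_of_max` break toward the smaller |angle|.
* Zero-variance inputs to the correlation raise an error rather than
  returning NaN.
* All catches must be positive; degenerate stimuli (zero integral) are
  rejected with a named error.

## Known limitations

Curved lamellae are treated statistically by the generator, not
electromagnetically (no FDTD/RCWA); polarization-resolved appearance and
oil-droplet/ommatidial spatial sampling are out of scope; indices carry no
dispersion or absorption; and the forestshade illuminant is a documented
construction, not a standard tabulation. These bounds are deliberate: they
keep every quantitative claim of the package inside what the test suite
and `scripts/acceptance.R` actually compute.
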