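# heliris

Structural colour analysis of *Heliconius* butterfly wing scales: an R
pipeline linking the nanostructure of wing-scale ridges to the iridescent
colour that birds and butterflies perceive.

The iridescent blue-green of several *Heliconius* species comes from
multilayer interference in the lamellae stacked along the longitudinal
ridges of each wing scale. `heliris` is written for researchers in
biophotonics and visual ecology who need to run (or audit) the complete
chain from raw measurements to perceptual conclusions:

* **Spectra** — angle-resolved reflectance processing: local-regression
  smoothing with negatives clamped to zero, min-zero normalisation,
  averaging, and extraction of peak wavelength, FWHM, maximum reflectance
  and angle of maximum over the 300–700 nm bird/butterfly visible range.
* **Optics** — the ridge multilayer as a periodic stack of
  refractive-index/thickness layers: the first-order
  constructive-interference condition
  λ₁ = 2 Σᵢ dᵢ √(nᵢ² − sin²θ) and the exact transfer-matrix reflectance
  R(λ, θ) for s/p/unpolarized light.
* **Periodicity** — ridge spacing estimated two independent ways: from
  2-D SAXS detector images (q = 4π sinθ/λ mapping, azimuthal radial
  integration, power-law background subtraction, refined peak position,
  d = 2π/q) and from AFM height maps (plane de-trend, Hann window, 2-D
  FFT power spectrum, azimuthal integration, dominant spatial frequency).
* **Vision** — receptor-noise-limited discriminability: A1 pigment
  templates from λmax, von Kries quantum catches under D65 or forest
  shade, tetrahedral/Maxwell colour coordinates, and chromatic JNDs from
  the noise model with eᵢ = w√(η_L/ηᵢ) plus achromatic JNDs
  |ln(Q_a,L/Q_b,L)|/w, for an avian violet-sensitive system and the four
  *Heliconius* receptor phenotypes (types I–IV).
* **Statistics** — per-taxon summary tables (mean ± s.d.) and the
  ridge-spacing vs brightness Pearson correlation with clade-wise OLS
  slopes.
* **Synthetic data** — seeded generators for angle-resolved spectra
  (transfer-matrix signal × Gaussian angular envelope + noise), SAXS
  images (Debye–Scherrer ring + power-law background + Poisson noise +
  beam stop) and ridged AFM maps (flat/curved profiles, sawtooth
  discontinuities), so the whole pipeline runs and is tested without any
  instrument files.

## Worked example

The measured ridge cross-section of the brightest iridescent taxon
(*H. sara*) has a 119 nm air / 85 nm chitin (n = 1.56) unit cell:

```r
library(heliris)

st <- sara_ridge_stack()
st
#> <multilayer_stack> 2-layer unit cell x 2, ambient n=1, substrate n=1.56
#>   n = 1     d = 119 nm
#>   n = 1.56  d = 85 nm
#>   period 204 nm
bragg_peak_wavelength(st, 0)
#> [1] 503.2
```

A 204 nm period and a first-order reflected wavelength of 503.2 nm — i.e.
the measured nanostructure predicts the blue-green reflectance peak
observed on the wing.

Ridge spacing round-trips through both synthetic instruments:

```r
img <- gen_saxs_image(812, seed = 1)           # Debye-Scherrer ring at 2*pi/812
ridge_spacing_from_profile(radial_integrate(img))
#> [1] 810.3588
afm_ridge_spacing(gen_height_map(812, seed = 1))
#> [1] 811.2966
```

Both recover the 812 nm input to well under 1 %. The taxon-level
association between ridge spacing and brightness, on the transcribed
study table:

```r
res <- spacing_reflectance_analysis(table1_fixture())
res$r; res$p; res$slopes
#> [1] -0.8285587
#> [1] 0.02125537
#>       erato   melpomene
#> -0.08287258 -0.02238148
```

Denser ridges mean brighter wings (r = −0.829, p = 0.021, n = 7), with a
steeper slope in the *erato* clade than in the *melpomene* clade. And the
perceptual end of the chain — how different two ridge multilayers whose
period differs by 8 nm look to a bird versus a butterfly:

```r
vs <- builtin_visual_systems()
a <- reflectance_spectrum(st)
b <- reflectance_spectrum(multilayer_stack(list(layer(1, 115),
                                                layer(1.56, 81))))
qa <- quantum_catches(a, vs$avian_vs, von_kries = FALSE)
qb <- quantum_catches(b, vs$avian_vs, von_kries = FALSE)
chromatic_jnd(qa, qb, vs$avian_vs)
#> [1] 0.9754616
```

About one just-noticeable difference for the avian predator (values above
1 are discriminable), while the same pair under the *Heliconius* type I
eye gives 1.93 JND.

## Command line

A thin dispatcher over the same functions is installed at
`inst/scripts/heliris` (`process-spectra`, `spacing`, `simulate`,
`config-show`), driven by a JSON run configuration
(`read_run_config()` / `show_config()` print every default).
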