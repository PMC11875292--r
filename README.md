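# sfdiq — quantitative SFDI and attenuation-corrected fluorescence

`sfdiq` processes spatial frequency domain imaging (SFDI) data into absolute
tissue optical-property maps and attenuation-corrected fluorophore
concentration maps. It is aimed at biomedical-optics groups doing
photodynamic-therapy dosimetry and light-triggered drug-release monitoring,
where raw fluorescence is confounded by tissue absorption and scattering: a
strongly absorbing tumor that holds *more* drug can look *darker* in raw
fluorescence. The package turns structured-illumination reflectance stacks
into per-pixel μa / μs′ maps, uses them to undo the attenuation, and reports
concentration in μg/mL with ROI statistics for photobleaching and release
kinetics.

## The model at the core

Reflectance of a spatially modulated source on a semi-infinite turbid medium
(diffusion approximation, partial-current boundary):

    Rd(fx) = 3 A a′ / [(μeff′/μtr + 1)(μeff′/μtr + 3A)]

with μtr = μa + μs′, a′ = μs′/μtr, μeff = √(3 μa μtr),
μeff′(fx) = √(μeff² + (2π fx)²), and A = (1 − Reff) / (2 (1 + Reff)) from the
refractive-index mismatch. Three-phase demodulation gives the per-pixel
modulation amplitude; a reference phantom of known properties calibrates it
to absolute Rd; a vectorised Levenberg–Marquardt fit inverts Rd(fx) per pixel
for (μa, μs′).

Fluorescence is corrected with the 1D effective-pathlength factor

    X1D(ex, em) = L(μa, μs′) / L(ref),   L = 1 / (μeff,ex + μeff,em)

normalised so X1D = 1 under the calibration phantom's optics, then
`F_corr = F_raw / X1D` is converted to μg/mL through a phantom calibration
line. See `vignette("sfdi-quantitative-fluorescence")` for assumptions,
parameter defaults and numerical choices.

## Worked example

A synthetic 64 × 64 scene with a tumor disc (μa 1.3 vs 0.6 cm⁻¹, μs′ 20 vs
12 cm⁻¹, fluorophore 3 vs 2 μg/mL), imaged at 5 spatial frequencies
(0–2.5 cm⁻¹) with 1% camera noise and calibrated against a (0.5, 10) cm⁻¹
reference phantom:

```r
library(sfdiq)
fx  <- frequency_set(seq(0, 2.5, length.out = 5))
ref_props <- optical_properties(0.5, 10)

# ... build `scene` and a flat reference scene (see the vignette), then:
ref <- reference_phantom(
  demodulate(render_reflectance_stack(ref_scene, fx, noise = noise(1))),
  list("490" = ref_props, "590" = ref_props))
rd  <- calibrate_reflectance(
  demodulate(render_reflectance_stack(scene, fx, noise = noise(2))), ref)
fit <- fit_optical_properties(rd)
fit
#> SFDI optical-property fit: 64 x 64 px, 2 wavelength(s), 5 frequencies, n = 1.4
#>   converged: 100.0% of pixels

fr   <- render_fluorescence_frame(scene, 490, 590,
                                  list(slope = 1500, intercept = 0),
                                  ref_props, ref_props, noise = noise(3))
x1d  <- correction_factor_map(fit, 490, 590, ref_props, ref_props)
cal  <- fit_fluor_calibration(c(2, 4, 6, 8), 1500 * c(2, 4, 6, 8))
conc <- to_concentration(correct_fluorescence(fr$f_raw, 0, x1d), cal)
```

ROI analysis of the result prints:

```
raw fluorescence tumor/periphery ratio: 0.78
tumor concentration: 2.76 +/- 0.43 ug/mL (n = 576)
periphery concentration: 2.00 +/- 0.06 ug/mL
concentration contrast ratio: 1.38
```

Read: the raw fluorescence ratio is **0.78** — the tumor looks dimmer than
its surroundings even though it holds 1.5× the fluorophore, because its
higher absorption shortens the effective path length. After correction the
concentration map restores the true positive contrast (**1.38** over a
square ROI that includes some rim pixels; the disc itself is 3 vs
2 μg/mL). The periphery recovers its ground-truth 2.00 μg/mL.

`percent_change()` and `contrast_ratio()` cover the bookkeeping around
photobleaching and release: e.g. a pre/post pair of 1.57 → 0.73 μg/mL is a
53.5% photobleaching decrease, and 6.53 → 13.01 μg/mL is a 1.99-fold
release increase.

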