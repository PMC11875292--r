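---
title: "Quantitative SFDI and attenuation-corrected fluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SFDI and attenuation-corrected fluorescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdiq)
```

# The measurement problem

Raw fluorescence imaged at a tissue surface is a poor proxy for fluorophore
concentration: the excitation light is attenuated on its way into the tissue
and the emission on its way out, both by amounts that depend on the local
absorption coefficient $\mu_a$ and reduced scattering coefficient $\mu_s'$.
A tumor that both absorbs more light *and* contains more drug can therefore
appear *darker* than its surroundings in raw fluorescence. Spatial frequency
domain imaging (SFDI) solves this by measuring $\mu_a$ and $\mu_s'$ per
pixel from structured-illumination reflectance, then using those maps to
undo the attenuation and report absolute concentration in $\mu$g/mL. The
package implements that chain end to end, plus region-of-interest analysis
of photosensitizer photobleaching and light-triggered drug-release kinetics,
and a synthetic-acquisition generator so every stage is testable without an
instrument.

# Forward model

The reflectance model is the standard diffusion approximation for a
spatially modulated planar source on a semi-infinite homogeneous medium.
With transport coefficient $\mu_{tr} = \mu_a + \mu_s'$, reduced albedo
$a' = \mu_s' / \mu_{tr}$, $\mu_{eff} = \sqrt{3 \mu_a \mu_{tr}}$ and
$\mu_{eff}'(f_x) = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}$:

$$R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)\,(\mu_{eff}'/\mu_{tr} + 3A)},
\qquad A = \frac{1 - R_{eff}}{2\,(1 + R_{eff})}$$

where $R_{eff} \approx 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$ encodes the
refractive-index mismatch at the boundary (partial-current boundary
condition). Frequencies are quoted in cm$^{-1}$ of the projected pattern;
the model consumes the radial frequency $2\pi f_x$. The planar $f_x = 0$
case is the same expression with $\mu_{eff}' = \mu_{eff}$, so the model is
continuous at DC.

```{r}
forward_reflectance(0.8, 15, fx = c(0, 0.5, 1, 2), n = 1.4)
```

The default refractive index is $n = 1.4$, typical for soft tissue, and
configurable everywhere it enters.

Two properties worth knowing:

* $R_d$ decreases strictly with $f_x$ — high frequencies probe shallow,
  scattering-dominated transport, which is what lets multi-frequency data
  separate $\mu_a$ from $\mu_s'$.
* $R_d$ decreases strictly with $\mu_a$ only while the modulation period
  stays above the transport length (roughly $2\pi f_x \lesssim 2\mu_{tr}$).
  Beyond that the model's absorption sensitivity degenerates; this is a real
  feature of the diffusion solution, not an implementation artifact, and the
  package's property tests assert monotonicity within the validity regime
  only. Measurement frequency sets in practice (0–3.2 cm$^{-1}$ against
  $\mu_{tr} \ge 10$ cm$^{-1}$) sit comfortably inside it.

The test suite verifies the closed form against an independent
finite-difference solve of the same diffusion boundary-value problem (Robin
partial-current boundary, Richardson extrapolation) to $10^{-6}$ relative
accuracy on a parameter grid.

# Demodulation

Each (frequency, wavelength) is acquired at three phases
$(0, 2\pi/3, 4\pi/3)$. The AC and DC amplitudes are

$$M_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1 - I_2)^2 + (I_2 - I_3)^2 + (I_3 - I_1)^2},
\qquad M_{DC} = \frac{I_1 + I_2 + I_3}{3}$$

computed after dark-frame subtraction (negatives clamped to zero, counted in
a message). This estimator is exactly the least-squares amplitude of the
three-point sinusoid fit and is invariant to the global phase of the
pattern. Pixels at the detector full scale (default $2^{16}-1$) in any phase
frame are flagged in a saturation mask and excluded from all downstream
fitting — demodulating a clipped sinusoid biases the amplitude. The DC
channel used downstream is the $f_x = 0$ frequency's own AC-style estimate,
keeping every frequency on the same estimator.

A physical-sanity diagnostic warns when $M_{DC} < M_{AC}$; it is evaluated
on the modulated frequencies only, because a fully modulated planar channel
has $M_{DC} = M_{AC}$ by construction and noise would trip the check half
the time there.

# Reference-phantom calibration

Dividing the sample's demodulated amplitude by that of a phantom with known
optical properties, measured under identical settings, cancels the
instrument throughput and illumination profile:

$$R_{d,sample}(f_x, \lambda) = \frac{M_{AC,sample}}{M_{AC,ref}} \cdot
R_{d,model}\!\left(f_x;\ \mu_a^{ref}(\lambda), \mu_s'^{ref}(\lambda)\right)$$

The default uses the per-pixel phantom amplitude (corrects illumination
non-uniformity); `ref_mode = "mean"` averages the phantom field first, which
is identical on a flat field and cheaper. Reflectance values above 1 are
non-physical and are masked rather than clipped — masked pixels propagate as
`NA` through every later map and are never in-filled.

# Per-pixel inversion

`fit_optical_properties()` recovers $(\mu_a, \mu_s')$ at every pixel and
wavelength by least squares over all available frequencies. Numerical
choices:

* **Optimiser.** A damped Gauss–Newton (Levenberg–Marquardt) iteration in
  log-parameter space, run *simultaneously across all pixels* with the
  $2 \times 2$ normal equations solved in closed form. Log parameters keep
  iterates positive and well scaled; steps are clamped to box bounds
  (defaults $\mu_a \in [10^{-3}, 5]$, $\mu_s' \in [1, 100]$ cm$^{-1}$,
  spanning tissue and the calibration-phantom range with margin). The
  vectorised design is what makes a 128 × 128 × 9-phantom validation run in
  seconds without compiled code; it is cross-checked in the tests against
  per-pixel `optim(L-BFGS-B)` and against a dense grid-search oracle.
* **Initialisation.** $(\mu_a, \mu_s') = (0.5, 15)$ cm$^{-1}$ by default.
  The DC end of the curve pins absorption and the high-frequency end pins
  scattering, so the objective is benign; an optional coarse
  $20 \times 20$ log-grid pre-scan (`prescan = TRUE`) guards degenerate
  curves.
* **Convergence.** Relative residual change and step size below $10^{-8}$
  (tolerance) or 200 iterations. Pixels whose damping saturates, or with
  fewer than two usable frequencies, are marked unconverged and carry `NA`.
  A fit pinned to both bounds simultaneously is treated as degenerate.
* **Binning.** Optional mean-pooling of the reflectance maps before fitting
  (`binning = 8` mirrors common laparoscopic practice) trades resolution for
  noise and runtime.

The result is a classed model object with the usual accessors:

```{r}
fx <- frequency_set(seq(0, 2.5, length.out = 5))
scene <- synthetic_scene(matrix(0.8, 24, 24), matrix(15, 24, 24), 660)
ref_scene <- synthetic_scene(matrix(0.5, 24, 24), matrix(10, 24, 24), 660)
ref <- reference_phantom(demodulate(render_reflectance_stack(ref_scene, fx)),
                         list("660" = optical_properties(0.5, 10)))
rd <- calibrate_reflectance(demodulate(render_reflectance_stack(scene, fx)), ref)
fit <- fit_optical_properties(rd)
summary(fit)
```

# Attenuation-corrected fluorescence

Modelling the excitation fluence as $e^{-\mu_{eff,ex} z}$ and the emission
escape as $e^{-\mu_{eff,em} z}$, the detected signal from a uniformly
fluorescent semi-infinite medium is proportional to the 1D effective path
length $L = 1/(\mu_{eff,ex} + \mu_{eff,em})$. The correction factor is this
path length normalised to the calibration phantom's optical properties,

$$X_{1D}(ex, em) = \frac{L(\mu_a, \mu_s')}{L(ref)},$$

so $X_{1D} = 1$ exactly under calibration conditions and all absolute scale
lives in the calibration curve. Corrected fluorescence is
$F_{corr} = F_{raw}/X_{1D}$ after dark subtraction. This deliberately omits
boundary ($A$, $R_{eff}$) terms — they are common to both legs and absorbed
by the normalisation — and the formula sits behind a single interface
(`correction_factor()`) so a more elaborate empirical pathlength model could
be swapped in without touching the rest of the chain.

Concentration conversion inverts an ordinary least-squares calibration line
fitted to corrected fluorescence of phantoms at known concentrations
(`fit_fluor_calibration()`, warning below $r^2 = 0.98$); negative
concentrations are clamped to zero with a logged count. Autofluorescence is
subtracted as a pre-injection background map or ROI scalar, with the
background-to-signal fraction reported as a diagnostic and a warning when
background dominates more than half the ROI.

# ROI analysis and kinetics

ROIs are polygons rasterized by the even-odd rule at pixel centers (a
deterministic stand-in for interactive hand-drawn outlines), or explicit
masks. Statistics use the population standard deviation (divide by $n$).
`percent_change()` reports $100\,(pre - post)/pre$, so positive values are
decreases (photobleaching) and negative values increases (release);
`contrast_ratio()` is the plain ratio of ROI means. `release_curve()`
summarises a time series of concentration maps and finds the plateau: the
earliest time point from which every remaining consecutive relative
increment stays below a threshold (default 2%, configurable). The final
time point alone never counts — otherwise every series would trivially
plateau at its last sample — so a strictly rising series reports the
plateau as not reached.

# The synthetic-acquisition generator

`render_reflectance_stack()` renders, per pixel and phase,
$I_k = dark + G\,[R_d(0) + R_d(f_x)\cos(2\pi f_x x + \phi_k)]$ with the
sinusoid along the column axis and the pixels-per-cm calibration declared in
the sidecar, so the demodulated amplitude equals $G\,R_d(f_x)$ *exactly* in
the noiseless case; the whole chain is verifiable against ground truth to
numerical precision. The gain default maps the peak modulated intensity of
an $R_d = 0.5$ pixel to 60% of full scale, leaving headroom so bright
phantoms do not clip while deliberate overdrive still exercises the
saturation mask. Noise is multiplicative Gaussian (a shot-noise proxy at
the 1% level used throughout the validation suites) plus optional additive
read noise, clipped to $[0, \textrm{full scale}]$, and fully seeded.
`render_fluorescence_frame()` is the exact inverse of the correction chain:
$F_{raw} = X_{1D}\,(slope \cdot C + intercept) + background + dark$.
`make_phantom_suite()` produces the titration grid
($\mu_a \in \{0.5, 1.0, 1.5\}$, $\mu_s' \in \{10, 20, 30\}$ cm$^{-1}$ by
default) whose first point doubles as the calibration reference, and
`make_fluor_calibration_suite()` the fluorophore titration
(2, 4, 6, 8 $\mu$g/mL).

What the generator does *not* emulate — and hence what passing tests do not
establish about real acquisitions: optical blur and fiber-bundle comb
artifacts, specular reflections and vignetting, surface curvature and
height variation, layered media (a skin layer over a tumor biases recovered
properties), wavelength-dependent instrument response, and co-registration
error between time points (the pipeline assumes a fixed camera and rigid
subject). Synthetic validation demonstrates the correctness of the
*processing*, not the physics fidelity of any instrument.

# Problem sizes and runtime

The shipped validation suites use 128 × 128 flat phantoms for the
titration-grid accuracy check (the laparoscopic 5-frequency configuration,
1% noise, full per-pixel fitting with no binning), 24–48 pixel scenes for
heterogeneous end-to-end round trips, and 1–5 pixel curves for
optimiser-versus-oracle comparisons. These sizes were chosen so the entire
suite runs in well under a minute on a single core while still exercising
every code path at realistic noise levels; all of them scale up by changing
`shape` arguments only.

# Known limitations

* The diffusion model underlies both the inversion and the correction
  factor; in low-albedo or high-frequency regimes outside its validity the
  fits are well-defined least-squares answers but not accurate physics.
* $X_{1D}$ is a homogeneous semi-infinite 1D model: depth-varying
  fluorophore distributions and shallow excitation penetration (notably at
  blue wavelengths) violate it and bias absolute concentrations.
* No surface-profile or height correction is applied; curved surfaces
  modulate the effective illumination and are treated as flat.
* ROI statistics are descriptive (mean ± population SD); no inter-group
  hypothesis testing is provided.
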