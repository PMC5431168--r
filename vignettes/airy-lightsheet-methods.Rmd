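---
title: "Airy light-sheet simulation and bead-based characterization: methods"
author: "AirySheet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airy light-sheet simulation and bead-based characterization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AirySheet)
```

This vignette documents the science implemented in **AirySheet**: the
scalar-diffraction model for single- and two-photon light-sheet excitation
through a cubic (Airy) phase mask, the synthetic iSPIM bead-stack
generator, the bead-based characterization pipeline, and the numerical and
design choices behind each. Units throughout: µm for space, nm for
wavelength, fs for time, THz for optical frequency, radians for phase,
degrees for the scan angle.

## 1. The excitation model

### Pupil integral

A static light sheet is a line focus: a cylindrical lens compresses the
beam in one transverse direction, so the field in the (x, z) plane —
x the propagation axis, z the sheet-thickness axis, which coincides with
the detection optical axis — is a one-dimensional pupil integral,

$$E(x,z) = \int_{-1}^{1} A(u)\, e^{i\varphi_{\text{mask}}(u,\lambda)}\,
  e^{i k n_w x \sqrt{1-(\mathrm{NA}\,u/n_w)^2}}\, e^{i k\,\mathrm{NA}\,u z}\,du,$$

evaluated by trapezoidal quadrature over `nPupil` samples (default 1025).
`A(u) = exp(-(u/f)^2)` is the Gaussian pupil amplitude with fill factor
`f` (the beam's intensity-1/e² radius over the aperture radius);
the defocus phase uses the exact non-paraxial square root — at NA 0.3 the
quadratic approximation is already a percent-level error over hundreds of
µm, and the exact form costs nothing.

Two checks pin the quadrature down: at paraxial effective NA the waist
FWHM matches the closed-form Gaussian-beam expression
$\sqrt{2\ln 2}\,\lambda/(\pi\,\mathrm{NA_{eff}})$ with
$\mathrm{NA_{eff}} = f\cdot\mathrm{NA}$ to better than 2 %, and doubling
`nPupil` moves any reported FWHM by less than 0.5 %.

### The cubic mask and the pupil relay

The mask is a refractive cubic surface on fused silica. Its modulation
depth α is defined as the centre-to-edge phase in **full wave cycles at
532 nm** over the 3.5 mm aperture radius; the manufactured element carries
four regions with α = 3.5, 7, 14, 21. At other wavelengths the phase of a
refractive element scales with the wavenumber *and* the substrate
dispersion,

$$\varphi(u_m,\lambda) = 2\pi\,\alpha\,u_m^3\,
 \frac{\lambda_{\mathrm{ref}}}{\lambda}\,
 \frac{n_{\mathrm{sub}}(\lambda)-1}{n_{\mathrm{sub}}(\lambda_{\mathrm{ref}})-1}.$$

The pure-wavenumber approximation is available
(`cubicMaskPhase(..., dispersive = FALSE)`) but the exact form is the
default — it is what a refractive element physically does. Sellmeier
sources: Malitson (1965) for fused silica, Daimon & Masumura (2007, 20 °C)
for water; both are cross-checked in the tests against independent
tabulated values to four decimals.

A point that turned out to be load-bearing: the mask does not sit directly
in the objective pupil. It is imaged by a 2× relay onto the back aperture
of the 10×/0.3 excitation objective, whose pupil radius is
NA · f = 0.3 × 18 mm = 5.4 mm. The pupil edge therefore maps to mask
radius 5.4/2 = 2.7 mm < 3.5 mm, and the *effective* cubic depth seen
across the pupil is α · (5.4/7.0)³ ≈ 0.459 α (before the wavelength
scaling). Without this relay the simulated Airy resolutions come out
*worse* than the measured ones, which would contradict their role as
best-case estimates; with it, the α = 7 and α = 21 two-photon waist FWHMs
(1.84 µm and 2.57 µm at 780 nm, fill 1.0) sit at or below the measured
values, as they should. `effectiveCubicDepth()` and `airyTrajectoryApex()`
expose the geometry; `relayMagnification` and `objectiveFocal` are
configuration parameters.

### Pulsed (two-photon) excitation

Two-photon fluorescence is proportional to the time integral of the
squared instantaneous intensity, $S = \int |E(t)|^4 dt$. The pulse is
modelled as transform-limited Gaussian: spectral intensity FWHM
$\Delta\nu = 2\ln 2/(\pi\tau) \approx 0.441/\tau$, sampled uniformly in
frequency over ±3 intensity standard deviations (default 33–65 samples;
`nSamples = 1` is the CW limit and reduces bitwise to the squared
monochromatic intensity). Each spectral sample propagates with its own
wavelength-dependent mask phase, immersion index and defocus phase.

Dispersion compensation is emulated by removing the constant and
group-delay parts of the common spectral phase, referenced at the grid
point nearest (x = 0, z = 0) — the analogue of tuning chirped-mirror
bounces for maximum two-photon signal. Higher-order residual dispersion is
retained. The time reconstruction is a DFT on a window of 1/Δν_spacing.
Because the reconstruction is periodic and $\int|E(t)|^4 dt$ over one full
period is invariant under circular time shifts, the group-delay offset of
points far from the waist (the pulse front arrives ~4.5 fs/µm later in
water) wraps harmlessly. True aliasing — a *stretched* pulse filling the
window — is what the guard detects: any point whose $|E(t)|^4$ stays above
10⁻⁶ of its local peak over more than half the period raises an error, and
the default window (≥ 8 samples per spectral σ at 33+ samples) keeps
ordinary 5–250 fs pulses far from it.

For pulses below ~3 fs the ±3σ spectrum extends past the validity of the
water dispersion model (182–1129 nm); those samples are dropped with a
warning and the remaining band renormalized. Physically, water absorbs
strongly beyond ~1.4 µm, so the clipped band is also the transmitted band;
this only affects the sub-5-fs regime, where the package's claim is merely
that the PSF *starts* to depend on pulse duration.

## 2. Resolution metrics

* **Main-lobe FWHM** per propagation position x: global maximum of
  S(x, ·) along z, restricted to the contiguous region above half maximum
  (this excludes the Airy side lobes, consistent with only the main lobe
  contributing usefully to two-photon image formation); crossings located
  by linear interpolation, peak position refined by three-point parabolic
  interpolation. Lobes touching the grid edge are flagged censored.
* **FOV**: the length of the maximal contiguous x-interval containing the
  FWHM minimum where FWHM ≤ √2 × min FWHM. The measured quantity behind
  reported FOVs is never accompanied by an explicit criterion; the √2
  (confocal-parameter) convention is the natural choice because it reduces
  exactly to twice the Rayleigh range for a Gaussian beam. Intervals
  satisfied at the grid edge are reported as censored lower bounds.
* **MTF**: magnitude of the 1-D DFT of S(x₀, ·) along z, normalized to 1
  at zero frequency, frequency axis in units of 2 NA/λ.
* **Figure of merit**: (depth of field × sheet width)/axial resolution² —
  dimensionless and scale-invariant, 10,000 for a 300 × 300 µm sheet at
  3 µm axial resolution.

### Pupil-fill calibration

The experimental pupil fill is not a measured quantity. Two documented
settings are used: `fillFactor = 1.0` for best-case simulations, and a
calibrated value obtained by root-solving the simulator so the Gaussian
two-photon waist FWHM at 780 nm equals the measured 1.4 µm
(`calibrateFillFactor()`, which converges to ≈ 0.50). The calibrated fill
reproduces the measured ~30 µm Gaussian FOV with no further tuning, and is
used for FOV-ratio experiments; the same fill applies to the Airy legs,
since inserting the mask does not change the beam envelope.

## 3. The synthetic phantom

The generator emulates the bead-characterization experiment:
sub-diffraction polystyrene microspheres (0.2 / 0.4 µm) in agarose,
translated at θ = 45° through the static sheet in Δt = 92 nm steps, imaged
through a 20×/0.5 detection path onto a 6.5 µm-pitch camera (325 nm
sample-plane pixels).

Conventions (shared bit-for-bit with the analysis module): frames are
indexed (row, col), 0-based, positions are pixel-centre continuous
coordinates; the lateral scan component Δt sin θ drifts beads along the
camera **row** axis, the axial component Δt cos θ along the detection
axis z.

Per frame, a bead contributes brightness × S(x, z) photons — the sheet
response pre-smoothed along z by the bead size (σ = d/4) — rendered as a
pixel-integrated 2-D Gaussian of width σ(z) = √(σ₀² + (cz)²), with
σ₀ = 0.21 λ_em/NA the in-focus width and c = NA/(2 n) the geometric
defocus rate. Noise is Poisson on (signal + background) followed by
Gaussian read noise, seeded and reproducible; stacks are written as 16-bit
multi-page TIFF with a JSON sidecar.

What the phantom deliberately does **not** model: diffraction-accurate
detection PSFs (the parametric defocus model provides realistic broadening
only), scattering, photobleaching, stripe artefacts, refractive-index
mismatch. Passing end-to-end tests therefore demonstrates correctness of
the *pipeline* under known geometry and noise, not robustness to every
real-sample pathology.

## 4. The characterization pipeline

1. **Spot detection**: difference-of-Gaussians band-pass, local maxima
   above threshold with a minimum separation, sub-pixel refinement by
   intensity-weighted centroid (matching the centroid refinement of the
   particle-tracking toolkit the procedure is modelled on; a Gaussian fit
   adds nothing for FWHM work).
2. **Linking**: nearest-neighbour after subtracting the expected constant
   drift, ties broken by smallest residual; tracks shorter than 3 frames
   dropped (5 in the convenience wrapper, which suppresses noise-spawned
   tracks).
3. **Scan angle**: per-track lateral drift d (µm/frame) from a
   least-squares line fit; θ = arcsin(d/Δt); median across tracks.
   Recovered to ±0.3° on seeded phantoms.
4. **Deskew**: frame i shifted by −i·Δt sin θ/pixel along the row axis
   (linear interpolation, NA sentinel outside the sheared support);
   z-spacing Δt cos θ. Round-trip error on band-limited volumes < 1 % of
   peak.
5. **PSF extraction**: per bead, background = median of the lateral ROI
   perimeter ring per slice; the axial profile is the **laterally
   integrated flux** per slice. Two deliberate choices here: the flux sum
   is not clipped at zero (rectified read noise would add a positive
   pedestal that biases FWHMs wide), and the flux profile is preferred
   over the amplitude-at-centroid profile because a normalized defocus
   blur dims the peak by σ₀²/σ(z)², which biases the centroid-amplitude
   FWHM 15–20 % narrow; the amplitude variant remains available as
   `profile = "centroid"`. Measurements are labelled by a configurable
   subregion grid (default 3 × 3).
6. **Summary**: mean and Student-t 95 % confidence intervals (the standard
   small-n choice) over uncensored measurements; measured FOV by the same
   √2 rule applied to the per-x FWHM curve binned at 20 µm (bin width
   configurable).

End-to-end, stacks rendered from a known sheet return the sheet's
main-lobe FWHM within 10 % (sub-1 % noise-free) and the scan angle within
0.3°, and measured FWHM is monotone in α across Gaussian/α = 3.5…21
sweeps.

## 5. Deconvolution

Richardson–Lucy with FFT convolutions, chosen because the data are
non-negative counts and RL is the standard for light-sheet work; the
iteration runs on a reflectively padded, circularly convolved domain
(which conserves total flux exactly for a unit-sum PSF and avoids edge
ringing) and the cropped result is renormalized to the input flux.
Non-negativity holds at every iterate; a delta PSF reproduces the input
exactly. The sheet PSF varies along x, so a per-subregion mode accepts a
list of locally extracted PSFs, deconvolves overlapping x-blocks and
blends them with linear ramps; the default remains shift-invariant with
the waist PSF, since the spatial model behind the published deconvolution
is not specified. Iteration count defaults to 10 and is a user decision.

## 6. Problem sizes and determinism

Default grids are chosen so every computation in the test suite and the
acceptance script runs in seconds on one core: pupil quadrature 1025
samples, sheet grids of 10³–10⁵ points with the z-range sized by the
parabolic trajectory apex (`airyTrajectoryApex`), 33 spectral × 132 time
samples for pulsed runs, phantoms of 1–14 beads over 40–120 frames.
All stochastic steps (phantom positions, rendering noise) flow through a
single seed and restore the caller's RNG state; identical configuration +
seed reproduces identical output files.

## 7. Known limitations

* Scalar, one-dimensional pupil theory: no polarization, no vectorial
  high-NA corrections, no aberrations beyond the cubic term, no 2-D
  (two-axis) Airy masks, no Bessel/structured sheets.
* Sample-induced dispersion and scattering are out of scope.
* The detection path is a parametric Gaussian-defocus model; lateral FWHM
  numbers from phantoms characterize the generator's own blur model, not
  a diffraction-accurate widefield PSF.
* The Airy trajectory is parabolic only to ~0.2 µm over the central FOV:
  the Gaussian pupil envelope leaves a smooth residual around the vertex,
  so trajectory fits saturate near R² ≈ 0.998 while the fitted quadratic
  coefficient still matches the stationary-phase prediction to a few
  percent.
* The diffraction-limited sampling guard and the √2-FOV criterion are
  conventions, exposed as configuration, not physical constants.
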