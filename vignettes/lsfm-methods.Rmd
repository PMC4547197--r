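---
title: "Methods: the lsfmsim rendering model and its numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lsfmsim rendering model and its numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsfmsim)
```

## The physical model

`lsfmsim` renders optical sections of fluorescent voxel volumes by solving a
single-scattering form of the radiative transfer equation whose source term
carries an inelastic (wavelength-shifting) fluorescence channel next to the
ordinary elastic one. The historical baseline for that channel — a binary
absorption window (1 between 370 and 690 nm excitation) combined with a
single-Gaussian emission line — is included as `cerezo_absorption()`,
`gaussian_emission()` and `cerezo_redistribution()`, but the production
model replaces it with the measured photophysics of each dye:

$$P_f(\lambda \leftarrow \lambda_{ex}) \;=\; f_{ex}(\lambda_{ex})\,
  f_{em}(\lambda)\,\phi,$$

so the energy redistribution between excitation and emission wavelengths
follows tabulated excitation/emission spectra and the quantum yield rather
than an idealized window. Because fluorescence emission is isotropic, the
inelastic phase function is the constant $1/4\pi$.

Three specializations shape the whole implementation:

1. **Monochromatic, directional illumination.** The sheet is a single laser
   line traveling along $+x$, so the double integral of the general
   fluorescence source term (over incoming directions and excitation
   wavelengths) collapses to a point evaluation. The integrator is exact in
   those variables instead of Monte Carlo sampling them.
2. **Single scattering.** Light interacts with the medium exactly once
   between sheet and camera. Multiple scattering, diffraction, interference,
   polarization, quenching and photobleaching are out of scope; the camera
   path only attenuates (Beer–Lambert).
3. **No self-emissive media.** The emission term of the transfer equation is
   identically zero; all light originates in the sheet.

### Units

Geometry is in micrometres; cross sections in cm² and concentrations in
cm⁻³, so volume coefficients $\sigma N$ are in cm⁻¹. The µm↔cm bridge
(1 cm = 10⁴ µm) lives in one audited pair of helpers, and path lengths are
converted once per marching step. The film accumulates *photons*, not
radiance: an ideal orthographic detector with per-pixel area in cm², so
`detect_photons()` is the plain double midpoint sum over pixels and
wavelength bins. This makes the closed-form photon-count validation below a
direct equality, with no radiometric calibration constant anywhere else.

### Spectral conventions

All spectral quantities live on a shared `wavelength_grid()` — by default
300–800 nm in 5 nm bins with midpoint centers, covering the common laser
lines (355–561 nm) and visible emission. Conventions, chosen once and used
everywhere:

- $f_{ex}$ is **peak-normalized to 1**: a dimensionless efficiency relative
  to the best excitation line, which makes $\sigma$ the cross section *at
  the excitation peak*.
- $f_{em}$ is **normalized to unit wavelength integral**: a density per nm,
  so summing the source term over emission bins recovers
  $\phi\, f_{ex}(\lambda_{ex})$ exactly and photon budgets close.
- Reads outside a spectrum's support return 0 — spectra are physically zero
  far from their bands, so out-of-range queries are not errors.
- The excitation line is a scalar wavelength, not a one-bin spike spectrum,
  avoiding any bin-width ambiguity in the flux density.

The bundled GFP/RFP/CFP-like dyes are *synthetic* Gaussian-mixture
approximations with literature-plausible peaks, yields and cross sections
(their files are named `synthetic_*`); every experiment in the package is
written against whatever spectra are loaded, never against these particular
shapes. One consequence of Gaussian mixtures worth knowing: their tails are
nowhere exactly zero, so "no emission outside the band" holds only up to
$e^{-50}$-scale values; tests that need exact compact support construct a
truncated spectrum explicitly.

## The specimen and its samplers

The virtual specimen is an annotated fluorescent volume grid: per-voxel
concentration plus a per-voxel dye index into a fluorophore table (−1 =
non-fluorescent). Mixed-dye voxels are deliberately unsupported — one dye
per voxel mirrors how tagged structures are annotated. Phantoms are built
by solid voxelization of spheres and capped cylinders using the
voxel-center inclusion test; overlaps sum densities and the last-listed
shape wins the dye index (a deterministic, documented tie-break). The
synthetic neuron generator draws one soma sphere (radius uniform in
5–10 µm) and 3–8 tapering random-walk neurites per cell, one dye per cell —
it emulates the sparse, filamentous geometry of fluorescently tagged
neural tissue, *not* any real morphology database: there is no branching
statistics calibration, no synapses, and densities are uniform inside each
primitive. Passing tests on these phantoms therefore demonstrates correct
rendering physics on plausible geometry, not biological fidelity.

Density is sampled trilinearly from voxel-center values with zero padding;
dye by containing voxel. Two consequences matter numerically:

- The continuous density profile extends **half a voxel** beyond the grid
  and tapers linearly to zero there (the zero-padded interpolation support).
  The ray marcher therefore integrates over the grid bounding box inflated
  by half a voxel, which makes line integrals of voxelized solids exact
  (convolution with the interpolation kernel preserves the integral), and
  the dye lookup is clamped to the boundary voxel inside that shell.
- A voxelized cube is a slightly smeared cube. A light sheet sized exactly
  to the cube face leaves the smeared half-voxel fringe outside the slab
  unilluminated: a bias of $\approx v/(4l)$ per transverse dimension
  (1.25% per dimension at $v = 0.1$ µm, $l = 2$ µm). This is visible in the
  brightness validation below and shrinks linearly with voxel size.

## Illumination

The illumination train (beam expander, cylindrical lens, illumination
objective) is not simulated element by element; the sheet is modeled
directly as its product — a rectangular, uniform, single-wavelength
directional slab. `gaussian_beam()` quantifies when that is defensible: a
real Gaussian sheet has half-thickness $w(x) = w_0\sqrt{1 + (x/x_R)^2}$ and
is $\sqrt2$ (i.e. 41%) thicker one Rayleigh range from the waist, so
`rectangular_approximation_error()` reports the worst-case thickness
deviation over a field of view and flags when the slab model is poor. The
lateral (y) profile is uniform with hard edges — the literal reading of
uniform illumination power; no lateral falloff model is offered.

`photons` is the photon budget of one exposure; the in-slab flux density is
`photons / (thickness × height)` in cm⁻². Beer–Lambert attenuation of the
sheet along $+x$ is available (`attenuate = TRUE`) but **off by default**:
the validation experiments assume uniform, maximal excitation of optically
thin specimens, and the default specimen has no elastic scatterers. Sheet
position and camera focal plane are synchronized by the renderer on every
section — the scene assembler owns that contract, so a misconfigured camera
cannot defocus the sheet plane.

## Extinction and reabsorption

The extinction coefficient at a point is the elastic coefficient (a global
per-grid scalar, default 0 — the elastic scattering strength of cleared
tissue is a free config parameter, not something the model predicts) plus
fluorophore absorption $\sigma N(p)$ weighted by the relative excitation
efficiency at the wavelength in question:

- **Excitation path** (sheet attenuation): weight $f_{ex}(\lambda_{ex})$ —
  exact.
- **Detection path**: emission spans a band, and carrying a per-bin
  transmittance would break the fast per-dye factorization of the film
  accumulation (below). Instead the camera path uses a wavelength-flat
  effective reabsorption factor per dye,
  $\kappa = \int f_{ex}(\lambda) f_{em}(\lambda)\, d\lambda$ — the
  emission-weighted mean excitation efficiency, i.e. the spectral-overlap
  (inner-filter) strength. For the GFP-like dye $\kappa \approx 0.48$;
  Stokes shift keeps it well below 1. This is first-order exact in optical
  depth and can be switched off entirely (`attenuation = "none"`) for
  comparison against non-attenuating closed forms.

## The integrator

`integrate_ray()` and the batch engine behind `render_section()` march each
camera ray across the inflated grid bounds with step $\Delta s$ (default:
half a voxel), accumulating $T(p_i)\,S(p_i)\,\Delta s$ with the
transmittance evaluated at segment midpoints. Per-ray step counts divide
the traversed length exactly, so constant integrands are integrated without
quadrature error; an optional per-ray stratified offset (`jitter`)
decorrelates banding and makes discontinuous integrands unbiased in
expectation. Because the source factorizes per dye into
(scalar path weight) × (emission spectrum), the engine accumulates one
scalar per ray per dye and expands to the full per-pixel spectrum once per
render — spectral arithmetic costs one outer product instead of one vector
per step. Elastic light is monochromatic and is bin-averaged into the
excitation bin.

All randomness (pixel jitter, lens sampling, march offsets) derives from a
single seeded stream consumed in a fixed order by the single-threaded batch
renderer, so a render is a pure function of (scene, camera, seed); the
linearity test exploits this to demand *exact* proportionality of films to
the photon budget.

## Acquisition

The telecentric detection train is an orthographic camera with a finite
aperture. A base ray runs from the film point along the view axis; with an
open aperture the origin is displaced by a concentric-disk-mapped lens
sample and redirected through the base ray's focal-plane intersection. The
blur rule is telecentric similar triangles: circle-of-confusion radius
$= \text{aperture} \times |\Delta z| / \text{focus\_scale}$, independent of
magnification. No lens prescription is modeled — `focus_scale_um` is the
single free parameter standing in for one (default 25 µm, held fixed across
all experiments), and film size, pixel pitch and samples per pixel are
config-exposed. Aperture 0 is the exact pinhole-orthographic limit with
infinite depth of field. Emission filters are per-bin transmissions in
front of the film; the default notch blocks the laser bin ± one bin, which
removes elastically scattered excitation light while passing the emission
band.

## Validation experiments and their design

**Brightness validation.** A 2 µm homogeneous cube with
$\sigma = 3\times10^{-16}$ cm², centered on the crossing of the
illumination and detection axes, sheet cross-section equal to the cube
face, photon budgets $(1\ldots10)\times10^{12}$, imaged by two opposing
cameras at ±z on 128² films with 64 samples/pixel. The cube's $N = 10^{18}$
cm⁻³ and $\phi = 0.8$ are fixture choices (the optical depth
$\sigma N l = 0.06 \ll 1$ is asserted at run time, so uniform excitation
holds). Expected photons per detection plane:
$(1/4\pi)\, I \sigma N \phi l$. The simulated/analytic ratio lands near
0.962 at the default voxel size: −2.5% from the half-voxel fringe outside
the sheet (two transverse dimensions × 1.25%), −1.4% from κ-weighted
reabsorption on the detection path. Both effects are physical consequences
of the declared discretization and extinction model, not fit parameters;
the acceptance tolerance is 5%.

**Emission-SPD recovery.** Because the pipeline is linear in the spectrum,
the pixel-summed detected SPD of a single-dye specimen, peak-normalized,
must reproduce $f_{em}$ exactly, and amplitudes across excitation lines
(355, 405, 488, 561 nm) must scale as $f_{ex}$ — curves are normalized to
the one at the strongest excitation line, the instrument-style convention.
Observed deviations are at machine precision (shape) and below 0.1%
(amplitude), against a 0.02 / 2% tolerance.

**Blur vs sheet thickness.** The phantom is a set of fluorescent rods
*extruded along the detection axis*. This makes the zero-aperture control
exact: the per-area flux falls as 1/thickness while the illuminated column
grows as thickness, so a pinhole camera records the *same* image at every
thickness (observed spread < 0.01%), while an open aperture defocuses the
extra out-of-plane column sections and sharpness — mean squared image
gradient over squared mean intensity, a scale-invariant metric chosen here
(the underlying claim is qualitative) — falls strictly across 5, 7.5, 10,
12.5 µm sheets.

## Problem sizes and determinism

Default experiment scales (128² film; 64 spp for brightness, 8 spp
elsewhere; 0.1 µm voxels for the cube, 0.5 µm for phantoms) were chosen so
the full validation battery runs in minutes on a single CPU while leaving
Monte Carlo noise far below every tolerance; `ortho_camera()` accepts
1024²/32 spp for production-scale sections. All experiment runners are
seed-reproducible, emit machine-readable tables, and every CLI output
carries seed, config hash, and scaling metadata.

## Known limitations

- Single scattering and geometric optics only: no multiple scattering,
  diffraction, interference, polarization or PSF model, so resolution
  effects below the blur-rule scale are absent.
- Detection-path reabsorption is wavelength-flat per dye (κ); strongly
  overlapping dyes in deep, dense specimens would need per-bin extinction.
- The uniform slab ignores beam divergence inside the field of view; use
  `rectangular_approximation_error()` to bound the error for a given
  waist and FOV.
- Phantoms are geometric primitives with uniform labeling; no noise model
  (shot/read) is applied at the detector — films are ideal.
- The elastic medium mask follows the (clamped) voxel dye annotation, so an
  elastic slab is effectively one voxel thicker than its nominal bounds;
  oracle tests account for that support explicitly.
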