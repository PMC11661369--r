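---
title: "phantomforge: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phantomforge: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phantomforge implements the digital half of a phantom-fabrication workflow in
which tissue-mimicking optical phantoms are 3-D printed by mixing gray
(absorbing), white (scattering) and translucent PLA filaments on the fly in a
multi-filament fusion extruder.  This vignette records the models the package
implements, the assumptions behind them, the tunable parameters that matter,
and the design decisions taken where the design was genuinely open.  It states
no empirical result that the test suite does not itself compute.

## The linear filament-mixing model

The central calibration object is a linear mixing law for each optical
property,

    mu = A * Rg + B * Rw + C,

where `mu` is either the absorption coefficient `mua` (1/mm) or the reduced
scattering coefficient `musp` (1/mm), and `Rg`, `Rw` are the volume
percentages (0-100) of gray and white filament; the translucent fraction is
the simplex remainder `Rt = 100 - Rg - Rw`.  The rationale is Beer's law:
absorption of a chromophore mixture is linear in the volume fractions, and the
same ansatz is extended to reduced scattering.  The intercept `C` is the
property of the pure translucent filament and must be positive to be
physically meaningful; a non-positive fitted intercept warns rather than
fails, because noisy calibrations can legitimately produce one.

**Fitting.** `fit_linear_mixing()` performs unweighted ordinary least squares
of the measured property against `(Rg, Rw)` with intercept.  The source
workflow describes only "linear regression", so unweighted OLS is the default;
inverse-variance weighting by the per-record ROI dispersion is available
(`weighted = TRUE`) but off by default, since median-based ROI summaries make
the homoscedastic assumption reasonable and the unweighted fit is the more
reproducible convention.  `R^2` follows the standard `1 - SSres/SStot`
convention about the mean of the measured values.  At least three records and
a non-collinear `(Rg, Rw)` design are required; rank deficiency is reported
with the degenerate direction named.

**Inverse design.** `invert_mixture()` finds the ratio whose predicted
properties best match a target by minimizing the sum of squared *relative*
errors, `((mua(R)-Tm)/Tm)^2 + ((musp(R)-Ts)/Ts)^2`, subject to
`Rg, Rw >= 0`, `Rg + Rw <= 100`.  Relative errors are used so that `mua`
(order 0.01-0.5) and `musp` (order 0.5-4) contribute comparably; the target
value sits in the denominator so the objective is an ordinary quadratic, which
is minimized exactly (unconstrained normal equations, then each edge of the
constraint triangle in closed form).  The relative errors *reported* in the
result follow the validation-error convention `|measured - predicted| /
predicted` with the model value as denominator.  Integer rounding enumerates
the up-to-four integer neighbors of the continuous optimum on the simplex and
keeps the smallest objective, breaking ties toward larger `Rt` (less pigment).
A target is `feasible` when both relative errors at the continuous optimum are
below a configurable threshold, 5% by default — the same tolerance used when
design generators flag unprintable regions.

**Titration design.** The bundled 16-point titration design
(`default_titration_ratios()`: `Rg` in {0, 6, 12, 18} crossed with `Rw` in
{0, 12, 24, 36}, grouped as four 4-segment rulers) is the package's own
choice: the published table of ratios is not reproduced here, so a full
factorial in the low-pigment corner was chosen to span the property range the
characterized filaments produce in tissue-relevant measurements (`mua` up to
about 0.15/mm, `musp` up to about 2/mm).  Any non-collinear design with at
least three points calibrates the model; the factorial keeps the two slopes
independently identifiable.

Under 5% multiplicative measurement noise on this 16-point design the OLS
estimates are unbiased, and the acceptance suite checks exactly that: the
*mean* recovered coefficient over 100 seeded replicates is within 5% of truth
for all six coefficients.  Per-replicate 5% accuracy holds only for the
dominant absorption slope `A`; the white-filament absorption slope
(`B = 0.00095`/mm per percent) and the absorption intercept are so small that
their sampling standard deviation alone exceeds 5% — a property of the stated
world, not of the fit.

## White Monte Carlo transport and the reflectance LUT

Per-pixel optical properties are recovered from spatial-frequency-domain
imaging (SFDI) data through a lookup table of diffuse reflectance `Rd(mua,
musp, fx)` for a semi-infinite homogeneous medium.  The table is built from a
*single* White Monte Carlo run (`simulate_white_mc()`):

* pencil beam, normal incidence on the half-space, refractive index `n = 1.4`
  against air, Henyey-Greenstein anisotropy `g = 0.9` (both defaults follow
  the tissue/PLA values used by the reference instrument);
* steps sampled exponentially at a reference scattering coefficient
  `mus_ref` (default 10/mm, i.e. `musp_ref = 1`/mm); no absorption during
  transport;
* specular reflection handled by weight deduction (`((n-1)/(n+1))^2`
  exactly), internal reflection by the polarization-averaged Fresnel
  coefficient with total internal reflection beyond the critical angle;
* every escaping photon recorded with exit radius, total pathlength and
  residual weight.

Absorption is applied after the fact by weighting each detected photon with
`exp(-mua * L)`, and other `musp` values are reached by similarity rescaling
of all lengths by `mus_ref / mus_target` (`mus_target = musp/(1-g)`), so one
simulation serves the whole grid.  Similarity is exact for isotropic
scattering and a controlled approximation for `g = 0.9`; a direct run at the
target scattering agrees with the rescaled baseline to within Monte Carlo
error in the package's tests.

Two numerical choices matter and are exposed as knobs:

* **Pathlength cap** (`max_path_mfp`, default 2e4 transport mean free paths).
  White transport keeps photon weight constant, so the classical roulette
  never triggers; instead photons are terminated at a pathlength cap.  The
  survival tail of the return time of a 1-D diffusive walk decays as
  `t^(-1/2)`, so the discarded diffuse weight at the default cap is below 1%
  even at `mua = 0`, and is annihilated by `exp(-mua L)` for any absorption of
  practical interest (the energy-conservation acceptance test measures the
  detected fraction directly).
* **Condensed-history tail** (`iso_after`, default 50 scatters).  After `n`
  Henyey-Greenstein deflections the directional correlation is `g^n`
  (about 5e-3 at the default), so the walk is continued with isotropic
  deflections at the reduced rate `mus_ref * (1 - g)`.  This preserves the
  diffusion constant and the pathlength statistics while cutting the step
  count by roughly `1/(1-g)`; the package's tests compare against the pure
  Henyey-Greenstein mode (`iso_after = Inf`).  The per-photon records are
  unchanged in meaning.

**Radial binning and frequency projection.** Detected weight is binned into
0.1 mm annuli out to 50 mm; the overflow bin is tracked but excluded from the
order-zero Hankel quadrature `Rd(fx) = 2*pi * sum Rd(rho) J0(2*pi*fx*rho) rho
d rho`.  At the property range of the printable filaments, radii beyond 50 mm
carry a negligible share of the absorbed-weighted signal.  The default LUT
grids are `mua` 0.001-0.8/mm (60 log-spaced), `musp` 0.2-4.5/mm (50 linear),
`fx` {0, 0.1}/mm, covering the characterized filament range with margin; grid
ranges, photon count and seed are recorded in the LUT metadata and serialized
with it.

**Diffusion oracle.** `diffusion_rd()` implements the standard semi-infinite
diffusion solution in the spatial frequency domain with
`mueff' = sqrt(3 mua mutr + (2 pi fx)^2)` and the internal-reflection
parameter `A = (1-Reff)/(2(1+Reff))`, `Reff = 0.0636 n + 0.668 + 0.710/n -
1.440/n^2` (the Groenhuis/Egan-Hilgeman empirical form), so the oracle is
fully reproducible.  It is an *approximation*: at `fx = 0.1`/mm and
`musp` below about 1/mm (`fx` approaching a tenth of the transport
coefficient) it overestimates `Rd` by 10% and more relative to Monte Carlo.
The Monte-Carlo-versus-diffusion acceptance check therefore runs on
`musp` in {1.42, 2.5, 3.5}/mm with `musp/mua >= 50`, where the oracle is
valid; the mismatch below `musp = 1` is the oracle's breakdown, not a
transport defect, and the cross-model tests document it with a wider band.

## SFDI recovery

`sfdi_recover()` composes three stages, each exposed separately:

1. **Demodulation** of the three phase frames per frequency (offsets fixed at
   0, 2*pi/3, 4*pi/3): `AC = (sqrt(2)/3) sqrt((I1-I2)^2 + (I2-I3)^2 +
   (I3-I1)^2)`, `DC = (I1+I2+I3)/3` — exact for sinusoidal frames.
2. **Calibration** against a homogeneous reference phantom of known
   properties (default `mua` 0.0064, `musp` 1.42/mm, the silicone slab
   convention): `Rd_sample = (AC_sample/AC_reference) * Rd_model(reference)`,
   with `Rd_model` interpolated from the LUT.  Zero-amplitude reference
   pixels are masked, not propagated; any global illumination gain cancels.
3. **Inversion**: per pixel, the pair `(Rd(0), Rd(0.1))` is matched to the
   LUT.  Within one grid cell both reflectance surfaces are bilinear, so the
   two-equation system reduces to a quadratic in one local coordinate; every
   cell is solved *exactly* and the root closest to the best coarse node
   wins.  This avoids the optimizer pathology of nearly parallel
   iso-reflectance ridges at high absorption, and guarantees exact recovery
   at grid nodes and for any LUT-forward-synthesized input.  When no cell
   contains a crossing — the observation is outside the attainable set — a
   shrinking local search supplies the least-squares projection and the pixel
   is masked invalid when its relative residual exceeds `mask_rel_tol`
   (default 0.1).  No recovered value can leave the grid bounds.

No profilometric (height/angle) correction and no spatial smoothing are
applied: the workflow being modeled describes none.

## Synthetic data: the stated world

`synth_titration()` draws measured properties on the mixing plane and
perturbs them with multiplicative Gaussian noise (5% in the acceptance
scenarios — a realistic ROI-median dispersion for SFDI), additive noise, or
Poisson shot noise.  `synth_sfdi_frames()` renders three-phase frames as
`gain * Rd * (1 + cos(2 pi fx x + phase))/2`; the `(1+cos)/2` convention
keeps frames non-negative (the physical projector pattern equation is not
published, so this is the package's documented choice) and cancels in
calibration.  The reference frame set is synthesized with the same gain and
forward model.  What a green end-to-end test establishes is therefore
self-consistency of the pipeline plus the transport model — not camera
realism: vignetting, cross-polarizer leakage, projector nonlinearity and
height variation are deliberately outside the generator.  The cross-model
tests (diffusion-synthesized frames inverted through the Monte Carlo LUT)
probe model error, and behave as the oracle's validity domain predicts.

`toy_gcode()` emits minimal absolute-mode programs with `;REGION:` markers,
serpentine block order (so a 2x2 checkerboard of two mixtures yields exactly
three within-layer transitions) and closed-form extrusion totals.

## G-code post-processing

Region identity is carried by `;REGION:<label>` comment markers, written by
the design manifest — parsing arbitrary slicer output for region identity is
out of scope.  The dialect is absolute positioning, millimeters, absolute
extrusion; relative modes raise an unsupported-dialect error naming the
command.  Purge towers are planned one per unique mixture of the contiguous
model (15x15 mm footprint by default, within the workflow's 15x15-15x35 mm
envelope), placed on the +x side of the model bounding box with a 10 mm gap
and 5 mm spacing, active from the first layer through the last heterogeneous
slice.  At each mixture transition the post-processor lifts Z by the 0.3 mm
z-hop, travels x-then-y to the incoming mixture's tower, emits the mixing
commands (Marlin-style `M163 S<channel> P<weight>` + `M164 S0`; the weights
are the simplex fractions), extrudes the configured purge volume — by default
one full tower layer, footprint x layer thickness x 110% infill, converted to
filament length via the 1.75 mm cross-section — and returns.  Model moves are
never removed or reordered; the added extrusion equals exactly the purge
volume per transition times the transition count, which the tests assert.
Travel decomposition order is fixed x-then-y for byte-identical determinism.

## Phantom designs

Every printed dimension of the published designs is hard-coded (slab sizes,
inclusion diameters and thicknesses, bar sizes, cylinder depth offsets); the
layout coordinates that exist only graphically live in a single editable
`layout` argument with figure-matching defaults.  The quality-assurance slab
(9 x 9 x 0.5 cm) carries disks C1-C3 (15x background `mua`, 3x `musp`;
diameters 15/10/5 mm), C4 (25x, 3x; 5 mm), and two bar pairs (5 x 20 mm, 2x
`musp`, 6x and 12x `mua`), all 1 mm thick on the bottom face — five distinct
property sets including the background.  The tomography slab is read as
10 x 5 x 1.5 cm (the printed "10x 1.5 x 5" is inconsistent with its inclusions
spanning "the full 15 mm thickness"); its 16 inclusions and their eight
distinct property sets over the entire model (background included) follow the
figure-caption counting; since the figure's numeric values are not published,
the eight sets are package defaults chosen inside the printable range and
verified feasible under the bundled filament model.  The three-mixture
anatomical scenario ships as a stand-in geometry (`design_mouse_standin()`),
because the segmented-atlas mesh requires an external download; purge-planning
behavior (three towers active on every slice up to the last heterogeneous one,
even where only two mixtures print) is what the stand-in reproduces.

Meshes are generated analytically: faces are triangulated on a shared grid
with annulus strips around each inclusion footprint, so background meshes
with blind or through cavities are closed and 2-manifold by construction and
volumes are exact for the polygonal geometry (cylinders are 64-gons, 0.16%
area deficit).  Export is ASCII STL, millimeters, z-up — text output keeps
the artifacts diffable; the geometry is identical to a binary write.

## Serialization choices

Titration tables are CSV with a units comment line; models, LUTs, mixture
plans and mesh manifests are JSON; frames are 16-bit binary PGM (P5).  PGM
replaces the more conventional TIFF because the supported R toolchain here
has no TIFF/PNG codec; PGM is a standard, single-header grayscale format that
round-trips 16-bit counts exactly.

## Known limitations

* Transport is semi-infinite and homogeneous per pixel; layered media,
  finite slabs (the phantoms are 5-15 mm thick) and lateral coupling between
  regions are not modeled, so recovered properties near region boundaries
  inherit the usual SFDI partial-volume caveats.
* The mixing model is single-wavelength (635 nm) and batch-specific;
  recalibration is the intended workflow for other filaments.
* The G-code post-processor annotates and augments slicer output; it is not
  a slicer, and purge tower fill is a simple serpentine rather than a tuned
  infill pattern.
* Stringing, extruder-feed reliability and other physical print artifacts
  are outside the digital scope.
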