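---
title: "Methods: multi-flash and cross-polarised specular reflection removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-flash and cross-polarised specular reflection removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microflash)
```

## The problem

A miniature camera held a few millimetres above glossy tissue sees the
mirror image of its own illumination as a saturated specular glint. The
glint destroys local image content: the sensor clips, and no
post-processing of a single image can recover what was never recorded.
Two optical strategies exist. *Multi-flash* imaging acquires the scene
once per illumination fibre; since the glint is a mirror construction
between camera and source, it moves when the source moves, while the
diffuse scene stays fixed, so the corrupted pixels differ between
flashes and the stack jointly contains the whole scene. *Cross
polarisation* exploits that the surface reflection preserves the
illumination's linear polarisation while multiply-scattered diffuse
light does not, so crossed polarisers suppress the glint at a fixed
light cost.

This package implements both, plus the synthetic scene model used to
test them end to end.

## Multi-flash reconstruction

### Geometry

For a flat horizontal sample, a camera on the central axis and a fibre
at lateral offset $\mathbf{f}$ (both at height $h$), the glint sits at
$\mathbf{f}/2$ — the lateral midpoint of camera foot and fibre foot.
With the default four fibres at 2.4 mm radius the four glints form a
square of 1.2 mm half-diagonal, and any two glints are separated by at
least 1.7 mm. Provided each glint's saturated disc has radius below
half that spacing, the saturated sets are pairwise disjoint: every
pixel is clean in at least three of four flashes.

### Pipeline

`remove_specular_multiflash()` runs, per flash:

1. **Saturation masking** on the raw sensor image: pixels
   $\ge$ `sat_threshold` (default 0.98) are unreliable; the mask is
   dilated by `sat_dilation` px (default 1, square element) to exclude
   the clipped shoulder of the glint.
2. **Illumination flattening** (optional, on by default): divide by a
   Gaussian-blurred copy of the image and rescale to unit max. Each
   fibre shades the field differently; flattening makes flashes
   photometrically comparable before their gradients are mixed.
3. **Forward gradients**: $g_x[r,c] = I[r,c{+}1]-I[r,c]$ (zero in the
   last column), analogously $g_y$.

Across flashes, the **per-pixel, per-component median** of the unmasked
gradient values forms the composite. The median is the classic robust
choice for a glint that moves between exposures: if at most
$\lfloor (N-1)/2 \rfloor$ of $N$ flashes are perturbed at a pixel, the
median equals the clean value *exactly* (for $N = 4$ with one
perturbed flash the two middle order statistics are both clean, so even
the even-count mean-of-middle-two rule is exact). Where every flash is
masked the composite emits a zero gradient and the integration fills
the hole harmonically — the gradient-domain default for inpainting.
A `min_magnitude` composite rule is available as a config option.

The composite field $g$ is integrated by solving the discrete Poisson
equation $\nabla^2 I = \operatorname{div} g$ with the
backward-difference divergence that is the exact adjoint of the forward
gradients (their composition is the 5-point Laplacian). The solver
applies a type-I discrete sine transform on the $(M{-}2)\times(N{-}2)$
interior, divides by the Dirichlet Laplacian eigenvalues
$2\cos\frac{\pi k}{m+1} + 2\cos\frac{\pi l}{n+1} - 4$ (all strictly
negative, so the division is always well defined), and transforms
back. The Dirichlet boundary is pinned to the per-pixel median image of
the processed flashes: gradient integration is blind to the global
intensity offset, and the median image is the natural robust anchor —
which image the boundary *should* be pinned to is genuinely open, so the
choice is exposed as `boundary_mode`. All computation is double
precision; the DST is computed via an odd-extension FFT.

An optional log-domain path (`log_domain = TRUE`) takes gradients of
$\log(I + \epsilon)$ and exponentiates after integration. It converts
multiplicative illumination differences into additive offsets that the
gradient discards, but amplifies noise in dark pixels; it is off by
default and is exact on the identity check too.

### The identity validation

Feeding $N$ identical, unsaturated images through the pipeline (with
flattening off, since flattening deliberately rescales) must return the
input: the composite is the input's own gradient, its divergence is the
input's Laplacian, and the boundary is the input's border, so the solve
reproduces the input up to floating-point round-off. The acceptance
script measures this on a 256×256 rendered phantom image; the test
asserts max abs error below $10^{-9}$ and the measured value is of
order $10^{-13}$.

## Cross-polarisation model

`crosspol_acquire()` computes
$I = T^2\,[\,D/2 + S\,(1/\mathrm{CR} + \sin^2\delta)\,]$, clipped to
unit range. Assumptions, in the package's own terms:

- Diffuse light is **fully depolarised** (factor $1/2$ at the
  analyser). Partial repolarisation at shallow depths is not modelled.
- The specular component is **fully polarisation-maintaining** and
  leaks only through the finite extinction ratio $1/\mathrm{CR}$
  (default CR 1500) and the Malus term $\sin^2\delta$ for a crossing
  misaligned by $\delta$; a per-pixel `angle_map` can express the
  angular spread across a wide-aperture objective. The model exposes
  both leakage terms separately and takes no position on their split in
  any particular instrument.
- Both polarisers share pass-axis transmission $T$ (default 0.90),
  hence $T^2$.

The scalar `residual_hotspot_ratio()`,
$S\,(1/\mathrm{CR} + \sin^2\delta)\,/\,(D/2)$, is the Weber visibility
of a leaked glint against the cross-polarised diffuse background; a
glint survives as a hotspot when it exceeds a visibility threshold
(default 0.1, deliberately config-exposed — it is a perceptual choice,
not a physical constant). With $S = 10 D$ the ratio at perfect crossing
is $1/75 \approx 0.013$ (invisible); a very flat glossy surface with
$S = 200 D$ gives $0.27$ — the polarisers genuinely fail there, which
is why fibre hotspots persist on mirror-like phantoms while vanishing
on rougher real tissue.

## The synthetic phantom

`scene_spec()` describes the conditions all tests run under: a 10 mm
field (default 256×256 px; pixel pitch = field/grid), camera at 8.0 mm,
four fibres at 2.4 mm radius, a layered glossy phantom with 1 mm
circular features under 0/0.5/1.0/2.0 mm of overlying material, and
five illumination wavelengths (450/540/660/850/940 nm).

Per-wavelength effective attenuation (1/mm) defaults to
450→2.0, 540→1.5, 660→1.0, 850→0.55, 940→0.45 — strictly decreasing in
wavelength, which is the physically meaningful property; the magnitudes
are plausible placeholders because the phantom's true optical
coefficients are proprietary, and every scene can override them.
Feature visibility decays as $C(d) = C_0\,e^{-2\mu_{\mathrm{eff}} d}$
(round-trip attenuation through the top layer, the simplest lumped
diffuse-transport proxy) and feature edges blur with depth at
`blur_sigma_per_mm` (default 0.1 mm of Gaussian sigma per mm of
depth — modest scattering blur that leaves a 1 mm feature recognisable
at 2 mm depth, as NIR imaging of shallow features shows).

Defaults fixed once by forward calculation, and why:

- `background_albedo` 0.375 and `base_contrast` 1.4 put the feature
  peak at 0.9 — a bright, hard-tissue-like inclusion that stays safely
  below the 0.98 saturation threshold so masking never eats the
  feature. With the attenuation table above, these values place the
  2 mm-deep feature above a 0.1 Weber visibility threshold only at the
  NIR wavelengths: visible-light contrast at 2 mm is
  $1.4\,e^{-4\mu} \le 0.026$ while 940 nm retains
  $1.4\,e^{-1.8} \approx 0.23$ before blur losses.
- The specular lobe is $\exp(-(\rho/\sigma_s)^2)$ with
  $\sigma_s = h\sqrt{2/\hat n}$ and Phong-type exponent $\hat n = 800$,
  i.e. $\sigma_s = 0.4$ mm: a compact bump whose saturated disc (at
  `specular_strength` 2.0) has radius well under the 0.85 mm needed to
  keep the four glints' saturated sets disjoint. The analytic Gaussian
  profile was preferred over an exact $\cos^n$ lobe because its width
  is directly controllable; both give a compact saturating bump.
- Sensor noise is additive Gaussian before clipping, default
  $\sigma = 0.005$ (a quiet but not noiseless small-sensor figure),
  fully seeded: identical scene + seed renders bit-identical stacks.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: no photon-transport simulation (the
depth/wavelength law is a lumped exponential, not radiative transfer),
a perfectly flat surface (real tissue curvature moves and distorts
glints), no lens distortion, perfect inter-flash registration (a moving
probe breaks the composite), and a single glint per flash rather than
the many micro-glints of wet tissue.

## Numerical and design choices

- **Flat-field blur sigma.** The flattening divisor's Gaussian sigma
  defaults to one quarter of the image side (2.5 mm at the default
  scale). A divisor blurred at the feature scale absorbs the feature
  itself and biases its measured Weber contrast by several hundredths;
  at side/4 the shading and feature scales are separated. The trade-off
  is real and exposed: smaller sigma flattens shading better (the
  rendered fibre footprint spans an ~11× dynamic range, and
  self-flat-fielding leaves ~15% residual near the peak even at
  side/8), larger sigma preserves scene structure better.
- **Saturation masks come from the raw images**, not the flattened
  ones: clipping is a sensor property, and flattening rescales values
  away from the threshold.
- **Photometric frames for comparison.** RMSE against ground truth is
  computed after a least-squares affine (gain + offset) fit: the three
  acquisition strategies differ in absolute scale by construction
  (cross-pol carries $T^2/2$; normalised reconstructions are
  unit-max), so raw RMSE would mostly measure those known factors.
  Single-flash baselines are illumination-flattened first, and the
  simulated cross-pol image is divided by its (known) illumination
  footprint, so each method is judged on structure, not shading.
- **Common random numbers in the sweep.** `depth_wavelength_table()`
  renders every (depth, wavelength) cell with the same noise seed, a
  paired design that makes cell-to-cell contrast differences
  systematic rather than sampling noise; the monotonicity claims are
  about the optics, not about noise realisations.
- **Wavelength ties at zero depth.** With no overlying layer the
  attenuation term is $e^0$ for every wavelength, so surface contrast
  cannot increase with wavelength; monotonicity in wavelength is a
  property of buried features only, and the tests assert it for depths
  > 0 with ties (within noise) at depth 0.
- **Problem sizes.** The identity check runs at 256×256; the
  glint-elimination battery uses twenty 128×128 scenes; the full
  4-depth × 5-wavelength sweep runs at 160×160. The camera's pixel
  count is a free parameter of the simulation, and these sizes resolve
  every structure in the scene (the specular lobe spans ~6 px at the
  coarsest scale).

## Known limitations

- The composite assumes a *static* probe and scene across the flash
  sequence; there is no registration or motion compensation.
- Harmonic infill is the only treatment of pixels saturated in *all*
  flashes; overlapping glints leave a smooth, featureless patch.
- The cross-pol model is scalar intensity only — no Stokes/Mueller
  treatment, no wavelength dependence of the extinction ratio.
- Exposure selection is manual: the renderer and pipeline assume the
  chosen intensity saturates only the glint, never the diffuse scene.
- `solve_poisson_dense()` is an oracle, deliberately refused above
  64×64; the DST solver is the production path.
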