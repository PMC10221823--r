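# microflash

Specular surface reflections are the bane of close-range imaging of wet or
glossy tissue: a fibre-illuminated micro-endoscopic probe held millimetres
above the surface sees its own light source mirrored as a saturated glint
that obliterates the sub-surface features a clinician actually wants to
see. `microflash` implements, in R, the two optical strategies such probes
use to defeat glints, together with a synthetic phantom renderer that makes
both fully testable without any instrument:

- **Multi-flash gradient-domain reconstruction.** The scene is imaged
  several times, once per illumination fibre (four fibres concentric
  around the camera at 2.4 mm). Because the glint is a mirror image of the
  source, it shifts with the active fibre while the diffuse scene stays
  put. Per flash, saturated pixels are masked (`threshold 0.98`, dilated
  1 px) and forward-difference gradients taken; the per-pixel **median of
  the unmasked gradients** across flashes rejects the moving glint
  exactly wherever it corrupts a minority of flashes. The composite
  gradient field `g` is then integrated back to an image by solving the
  discrete Poisson equation

  ```
  ∇²I = div g,   I|∂Ω pinned (Dirichlet),
  ```

  with a type-I discrete sine transform, which diagonalises the
  Dirichlet interior Laplacian with eigenvalues
  `2cos(πk/(m+1)) + 2cos(πl/(n+1)) − 4`. Feeding four identical images
  through the full pipeline returns the input to ~10⁻¹³ max abs error —
  the standard self-consistency validation of the integrator.

- **Cross-polarised acquisition.** Crossed linear polarisers on source
  and camera block the polarisation-maintaining specular reflection while
  passing half of the depolarised diffuse light:

  ```
  I = T² · [ D/2 + S · (1/CR + sin²δ) ]
  ```

  with pass-axis transmission `T`, extinction (contrast) ratio `CR`
  (default 1500) and crossing misalignment `δ` (Malus leakage `sin²δ`).
  The residual-hotspot ratio `S·(1/CR + sin²δ) / (D/2)` predicts when a
  glint survives the polarisers — on a very flat glossy surface with
  `S ≈ 200·D` the ratio is 0.27, a clearly visible hotspot even at
  CR 1500.

The synthetic scene model renders a layered glossy tissue-mimicking
phantom: 1 mm circular features of raised albedo buried under 0–2 mm of
overlying material, feature contrast decaying as `exp(−2·μ_eff·depth)`
with a wavelength-dependent effective attenuation (450–940 nm; longer
wavelengths penetrate deeper), cos⁴θ·(h/r)² fibre illumination footprints,
saturating Phong-type glints at the camera–fibre midpoints, and seeded
sensor noise.

## Worked example

```r
library(microflash)

sc <- scene_spec(grid_size = 128, layer_thickness_mm = 0.5,
                 wavelength_nm = 850, rng_seed = 42)
stack <- render_flash_stack(sc)      # 4 flashes, glints shifted per fibre
rec   <- remove_specular_multiflash(stack)
summary(rec)
#> Multi-flash reconstruction summary
#>   flashes: 4  image: 128 x 128
#>   saturated fraction before/after: 0.005859 / 0
#>   masked fraction per flash: 0.00873, 0.00873, 0.00873, 0.00879
#>   vs ground truth: max abs 0.2128 , rmse 0.01975
```

Every raw flash saturates ~0.6% of its pixels at the glint; the
reconstruction has none, and its affine-matched RMSE against the known
clean diffuse image (0.0197) beats every single flash. Comparing the three
acquisition strategies on the same scene:

```r
compare_methods(sc)$metrics
#>         method saturated_fraction weber_contrast rmse_vs_truth
#> 1 single_flash             0.0058          0.541      0.023604
#> 2   multiflash             0.0000          0.764      0.019747
#> 3     crosspol             0.0000          0.750      0.000274
```

The buried feature's Weber contrast, washed out in the raw flash by the
glint and shading, recovers to ~0.75–0.76 under both correction schemes
(the 0.5 mm layer at 850 nm attenuates the intrinsic 1.4 surface contrast
to about 0.8). `depth_wavelength_table()` runs the full depth ×
wavelength sweep and shows that at 2 mm burial depth only the NIR
wavelengths keep the feature above a 0.1 visibility threshold.

A thin CLI over the same functions (subcommands `simulate`, `deflash`,
`crosspol`, `compare`, `sweep`, `metrics`) ships at
`inst/scripts/microflash.R`; stacks are written as multi-page TIFF or
numbered PNGs with a JSON sidecar.

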