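# cbctdir

Deformable image registration (DIR) between planning CT (pCT) and
kilovoltage cone-beam CT (kVCBCT) for adaptive radiotherapy of the pelvis,
with the full evaluation stack used to judge such registrations: TG-132
contour metrics, image-quality indices, DVH metrics and gamma analysis —
plus deterministic digital phantoms that supply all test data.

## The problem

Daily CBCT shows the anatomy of the day but its voxel values are too
distorted (scatter, noise, cupping) for dose calculation. The usual remedy
is a *deformed CT*: warp the planning CT onto the CBCT geometry so that
reliable CT numbers meet today's anatomy. Intensity-driven DIR, however,
fails precisely at the organs that change most — bladder and rectum — where
CBCT soft-tissue contrast is poor. `cbctdir` implements three strategies:

* **IOF** — iterative optical flow: a demons-type force
  `Δu = (F − M_w)∇M_w / (|∇M_w|² + α(F − M_w)²/s̄²)`
  accumulated into a displacement field u (pull convention,
  `warped(x) = moving(x + u(x))`), Gaussian-regularised after every pass,
  run over a multiresolution schedule (default: 5 iterations × 10 passes at
  full resolution, 30 × 50 at half resolution, σ = 1 mm on the DVF, two
  multigrid V-cycles).
* **Hybrid** — a three-level cubic B-spline registration (SSD metric) whose
  DVF initialises the optical flow.
* **Two-step** — contoured organs on *both* images first receive consistent
  synthetic intensities via the override `I′ = I − I_average + C`
  (C = 800/1200/800/1200 for bladder/target/rectum/subcutaneous fat, in
  offset units HU + 1000); the flow runs on the overridden pair; the
  resulting DVF then warps the *original* pCT, so the synthetic values never
  reach the deformed image.

Supporting pieces: treatment-table removal, bowel-gas detection (< 800
offset units) and paint-and-blend filling (to 1060), Dice / 95% Hausdorff
distance with an exhaustively verified surface-distance core, SNR / CNR /
uniformity / MAE / ME / PSNR / SSIM / identity-function profile, cumulative
DVHs with D98 / Dmean / Dmax / Vx, and a 3%/3 mm gamma index with sub-voxel
search.

## Worked example

Register a simulated treatment-day CBCT back to its planning CT and score
the propagated contours against the known truth:

```r
library(cbctdir)

# 1. simulate a planning CT and a treatment-day CBCT with known truth
ph <- make_pelvis_phantom(pelvis_phantom_config(seed = 17))
cbct <- degrade_to_cbct(ph$day_image, cbct_degradation_config(seed = 18),
                        body = ph$day_structures$masks$body)

# 2. preprocess: fill bowel gas on the CBCT
gas <- detect_gas_pockets(cbct, body = ph$day_structures$masks$body)
cbct <- fill_gas_pockets(cbct, gas)$output

# 3. fit the two-step registration (override -> optical flow -> warp)
fit <- dir_register(cbct, ph$pct, method = "twostep",
                    fixed_structures = ph$day_structures,
                    moving_structures = ph$structures)
print(fit)
#> Deformable registration fit (method: twostep)
#> grid_geometry: 96 x 96 x 48 voxels, spacing (1, 1, 2) mm, origin (0, 0, 0) mm
#>   SSD: 6.947e+09 -> 1.775e+09 (74.4% reduction)
#>   max |u| = 6.86 mm

# 4. propagate the planning contours and score them against the truth
prop <- predict(fit, ph$structures)
rep_ <- geometry_report(ph$day_structures, prop,
                        structures = c("bladder", "rectum", "target"))
print(rep_, digits = 3)
#>   structure   dsc hd95_mm msd_mm
#> 1   bladder 0.973       1  0.200
#> 2    rectum 0.930       1  0.420
#> 3    target 0.973       1  0.149
```

The phantom's "day" anatomy has a bladder 30% fuller and a rectum 15%
emptier than planning, a smooth random background deformation, bowel gas,
and CBCT-style degradation. After the two-step registration all three
structures sit at Dice ≥ 0.93 with a 95% Hausdorff distance of 1 mm —
comfortably inside the DSC ≥ 0.8 bar used to judge DIR fit for adaptive
replanning — whereas the plain intensity flow on the same case leaves the
bladder near its unregistered overlap. `residuals(fit)`, `summary(fit)` and
`plot(fit)` expose the intensity residual, the per-stage SSD log and a
mid-slice comparison.

A thin command-line wrapper is installed with the package
(`inst/cli/cbctdir`) with subcommands `run`, `phantom`, `register`,
`eval-geometry` and `eval-dose`; `run_pipeline()` drives the same workflow
from a YAML config.

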