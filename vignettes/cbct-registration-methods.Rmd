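---
title: "Deformable CT-to-CBCT registration for adaptive radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable CT-to-CBCT registration for adaptive radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdir)
```

# The problem

Image-guided adaptive radiotherapy (ART) of the pelvis re-evaluates a
patient's treatment using the kilovoltage cone-beam CT (kVCBCT) acquired on
the treatment machine. The kVCBCT shows the anatomy of the day — a fuller
bladder, an emptier rectum, gas in the bowel — but its voxel values are
unreliable for dose calculation because of scatter, noise and cupping. The
standard remedy is a *deformed CT* (dCT): the planning CT (pCT) warped onto
the day's geometry by deformable image registration (DIR), so that the
reliable CT numbers of the pCT travel to the CBCT geometry.

The difficulty is that intensity-driven DIR fails exactly where it matters
in the pelvis: organs with variable filling (bladder, rectum) have low
soft-tissue contrast on CBCT, and the registration either leaves their
boundaries misplaced or drags bowel content into them. `cbctdir`
implements and compares three strategies:

1. **Iterative optical flow (IOF)** — a demons-type intensity-driven flow,
   run multiresolution with Gaussian regularisation of the displacement
   field (DVF).
2. **Hybrid** — a multiresolution cubic B-spline registration (SSD metric)
   whose DVF seeds the optical flow.
3. **Two-step** — organ intensities on *both* images are first replaced by
   consistent synthetic values (the override below), the flow is run on the
   overridden pair, and the resulting DVF is applied to the *original*
   planning CT.

# Conventions

**Intensity units.** All images are carried in *offset units*, HU + 1000
(air 0, water 1000). The package's thresholds are only physically coherent
on that scale: gas is "below 800" (i.e. below −200 HU), gas pockets are
painted to 1060, and the override constants are 800–1200. Importers can
shift raw-HU volumes with `read_volume(..., shift_to_offset = TRUE)`.

**Geometry.** Voxel lattices are described by shape, spacing (mm) and the
world coordinate of the first voxel centre, in fixed (x, y, z) axis order;
interpolation happens at voxel centres. DVFs use the *pull* (backward-warp)
convention on the fixed-image grid: the warped image at world point
$x$ takes the moving image's value at $x + u(x)$, with $u$ in mm. The fixed
image is the kVCBCT and the moving image the pCT throughout the clinical
workflow.

# Preprocessing

**Table removal / body masking.** Outside-body content (the treatment
table) is removed either with a supplied body mask or by thresholding: the
body is the largest 26-connected component above the threshold, with
enclosed holes filled slice by slice (`remove_table()`).

**Gas-pocket filling** (`detect_gas_pockets()`, `fill_gas_pockets()`).
Bowel gas present on only one of the two images creates false
correspondence. Voxels strictly below 800 offset units form the gas mask
$M_1$; painting them to 1060 and Gaussian-smoothing gives the painted
image; $M_1$ dilated by a 2-voxel ball gives $M_2$, whose Gaussian blur is
the per-voxel blend weight $w \in [0,1]$:
$$\mathrm{output} = w \cdot I_{\text{painted,smoothed}} + (1-w) \cdot I_{\text{original}}.$$
Because the truncated Gaussian kernel has finite support, voxels away from
$M_2$ keep their original values bit-identically, and deep pocket interiors
become exactly 1060. The smoothing sigma is not dictated by the procedure's
description; the default of 2 mm spans the 2-voxel dilation band and is
configurable.

**Structure intensity override** (`override_structures()`). Inside each
contoured structure the intensity is replaced by
$$I' = I - I_{\text{average}} + C,$$
with $C$ = 800 (bladder), 1200 (target), 800 (rectum), 1200 (subcutaneous
fat) and $I_{\text{average}}$ the image mean. The shift preserves
within-structure texture (the SD is unchanged exactly) while forcing the
*same* organ to the *same* intensity band on both images, which is what
rescues the registration where CBCT contrast is missing. Two choices were
genuinely open and are configurable: the scope of $I_{\text{average}}$
(whole cropped image by default; body-mask option) and the priority for
overlapping masks (fixed order, target > rectum > bladder > subcutaneous
fat, the clinical priority of getting the target right).

# Registration

## Iterative optical flow

Each inner iteration warps the moving image $M$ under the current DVF and
adds the demons force
$$\Delta u = \frac{(F - M_w)\,\nabla M_w}{\|\nabla M_w\|^2 + \alpha (F - M_w)^2 / \bar s^2},$$
where $F$ is the fixed image, $M_w$ the warped moving image and $\bar s^2$
the mean squared voxel spacing — the ITK-style normalisation that bounds
each step near half a voxel. After every *pass* the DVF is smoothed with a
Gaussian of `dvf_sigma_mm` (default 1 mm). "Iterations" are the inner
update steps per pass; "passes" are the outer loops ending in DVF
smoothing — the two-level loop structure that optical-flow DIR tools use.

The default schedule is two stages — full resolution with 5 iterations and
10 passes, and half resolution with 30 iterations and 50 passes — plus two
closing multigrid V-cycles (a short coarse correction followed by a fine
sweep, with the DVF restricted/prolonged by linear interpolation between
grids). Stages are executed coarse-to-fine, the standard and stable order;
`listed_order = TRUE` runs them exactly as listed (fine first) for strict
reproduction of the stated sequence. Before a coarse stage both images are
Gaussian low-passed (sigma = scale/2 voxels) so that downsampling does not
alias texture — without this anti-alias pyramid the coarse stage cannot
establish correspondence.

The method contract is monotone: the returned DVF never has a larger SSD
than the initial field, enforced by tracking the best field seen. Constant
images (no gradient to drive the flow) return the initial field with a
warning.

## B-spline registration

A cubic free-form deformation over three coarse-to-fine levels
(control-point spacings 64/32/16 mm by default, image downsampling
4×/2×/1×), optimised by gradient descent with a backtracking line search on
the SSD. The level count is fixed at three and the metric is SSD (which
outperforms mutual information for same-patient CT-to-CBCT); the
optimiser, step sizes and control-point spacings are this package's own
defaults, chosen as reasonable FFD practice. An optional prealignment initialises the
lattice with the intensity-centroid translation. The final lattice is
densified to a per-voxel DVF (`cpp_ffd_dense`), which the tests check
against a direct tensor-spline evaluation.

## Hybrid and two-step

The hybrid method is exactly `iof_register(fixed, moving, init =
bspline_register(fixed, moving))`. The two-step method overrides both
images, registers the overridden pair with the optical flow, then warps the
*original* pCT with the resulting DVF — so the synthetic override
intensities never appear in the deformed CT, which the tests verify by
comparing bladder means before and after. Registering overridden-to-
overridden (rather than overridden pCT to raw CBCT) is the design here:
the override only helps if both images present the organ at the same
synthetic intensity.

# Evaluation metrics

**Contour agreement (TG-132 style).** Dice coefficient and 95% Hausdorff
distance. Surfaces are extracted on the voxel lattice (mask voxels with a
face neighbour outside), distances are Euclidean between surface-voxel
centres in mm, and the percentile is linearly interpolated on the sorted
directed distances. HD95 is reported symmetric (max of the two directed
percentiles) — the conventional TG-132 report — with a `directed = TRUE`
option for the one-sided variant. On masks small enough to enumerate, the
implementation agrees with an exhaustive all-pairs oracle to 1e-9 mm.

**Image quality.** SNR (mean/SD of an ROI), CNR ((insert − background
mean)/background SD), uniformity (largest relative deviation of peripheral
ROI means from the central ROI mean, percent), MAE/ME, PSNR
($20\log_{10}(\text{range}/\text{RMSE})$, range defaulting to the reference
max − min within the mask), Gaussian-window 3-D SSIM ($k_1 = 0.01, k_2 =
0.03$), and the identity-function profile (IFP): binned mean of deformed
intensity versus reference intensity, scored by the RMS deviation from the
identity line over occupied bins. The exact SNR/CNR/uniformity formulas
used in the reference workflow are not public; the standard definitions
above are adopted and stated so every reported number is auditable.

**Dose.** Cumulative DVHs; $D_{p\%}$ as the $(1 - p/100)$ quantile of the
voxel doses (linear interpolation), $D_{\text{mean}}$, $D_{\max}$, $V_x$
(percent volume at or above $x$ Gy); and a gamma analysis with 3%/3 mm
global criteria by default. The gamma search evaluates every candidate
displacement on a lattice (step 0.3 mm, radius 2·DTA) with trilinear
interpolation of the evaluated dose, and exploits the sorted candidate
list for the classic early exit. A voxel passes at $\gamma \le 1$ (the
boundary counts as a pass); voxels below the 10% low-dose threshold are
excluded by default (set the threshold to 0 for strict evaluation). The
normalisation is global (reference maximum) with a local option. One
source quotes 3.0%/0.3 mm in passing where the methods text twice says
3 mm; the 3%/3 mm criterion is the default and the other variant is
reachable through `gamma_params()`.

# The phantoms: what they emulate and what they do not

All test data are generated in code. The **disc phantom**
(`make_cirs_phantom()`) emulates a commercial electron-density phantom: a
water-equivalent disc, dense outer ring and tissue-equivalent inserts with
exact configured intensities, plus centre/peripheral ROIs for uniformity.

The **pelvis phantom** (`make_pelvis_phantom()`) builds a planning-CT-like
pelvis — elliptical body with an 8 mm subcutaneous fat shell (900), muscle
(1040), bladder (1010), target (1070), rectum (980), femoral heads (1400),
with smooth random soft-tissue texture (SD 15, 3 mm correlation) so the
flow has something to grip. The "treatment day" is produced by a synthetic
diffeomorphic DVF: organ-centred radial scalings realising the configured
volume-change factors (bladder ×1.3, rectum ×0.85 by default — a
substantial fill change of the kind that defeats intensity-only DIR)
composed with a smooth random global field (3 mm peak, 15 mm correlation),
integrated by scaling-and-squaring of the velocity field so the transform
is invertible and truth masks are well defined. Day masks are evaluated
*analytically* at the warped coordinates, so the ground truth carries no
interpolation bias. Optional gas pockets are inserted into the day rectum;
CBCT-style degradation adds cupping, a scatter offset and Gaussian noise
(SD 40 offset units by default — a realistic CBCT soft-tissue noise level).

What the phantom does **not** emulate: scatter that depends on anatomy,
reconstruction artefacts with angular structure, partial-volume effects at
interfaces, motion during acquisition, or contouring error (its "contours"
are exact). Passing the recovery experiment therefore shows that the
algorithms do what they claim under controlled, known-truth conditions —
not that clinical accuracy on patient data is guaranteed.

# Default experiment and problem sizes

The package's end-to-end experiment registers the default 96 × 96 × 48
phantom at (1, 1, 2) mm — a deliberately desk-sized volume that keeps the
full default schedule (both stages plus V-cycles) around half a minute per
registration while leaving organ structures several voxels of detail. The
test suite runs the full two-step and plain-flow registrations once on
this default case and checks: Dice ≥ 0.85 and HD95 ≤ 3 mm for bladder,
rectum and target after the two-step method, and a strictly higher mean
Dice than the plain flow on the same case — the qualitative ordering
(override helps, intensity-only does not) that motivates the two-step
approach, together with the TG-132 "DSC ≥ 0.8" bar for ART. Unit tests use
smaller textured volumes (16³–32³ grids) where properties are checked
against closed forms or brute-force oracles.

# Numerical choices and edge cases

* Trilinear interpolation everywhere; nearest-neighbour for label/mask
  resampling; masks propagated by linear warp + 0.5 threshold (guaranteed
  binary).
* Out-of-extent samples take a configurable background (default 0 = air).
* Gaussian filters are separable with mirror boundaries and kernels
  truncated at 3.5 sigma (hence exact zeros far from support — the
  property the gas-fill bit-identity guarantee relies on).
* Two empty masks have Dice 1 (with a warning); one empty mask is an error
  for surface distances.
* Identical volumes report infinite PSNR rather than an error.
* All generators and both registrations are deterministic given seeds;
  reruns are bit-identical, which the suite asserts.

# Known limitations

* Intensity-driven flow cannot recover the tangential component of motion
  in texture-free regions (the aperture problem); displacement fields are
  therefore evaluated through structure overlap rather than pointwise
  vector error, except where texture makes the truth identifiable (the
  recovery experiment additionally checks that the mean endpoint error of
  the recovered field inside the body stays below 2 mm).
* Voxelwise CT-number fidelity of the deformed CT is limited at
  high-contrast interfaces (bone, body surface): a residual misregistration
  of around one voxel produces errors of hundreds of offset units exactly
  there, which squared-error summaries (RMSE, PSNR) weight heavily. With
  the phantom's moderate CBCT degradation the deformed CT can therefore
  show an MAE comparable to the degraded CBCT's even when its organ
  geometry is far better — the geometric metrics, not PSNR, are the
  package's primary evidence of registration quality.
* The synthetic dose generator is geometry-driven; it cannot emulate dose
  errors caused by wrong CT numbers in a dose engine, which is the failure
  mode that makes raw-CBCT dose calculation unacceptable clinically. Gamma
  comparisons here measure propagated-geometry agreement only.
* The B-spline optimiser is a plain projected gradient descent; it is
  robust at the multiresolution settings shipped but not tuned for speed.
* NIfTI is the only on-disk dialect; DICOM series/RTSTRUCT import is out
  of scope (planar-contour rasterization from JSON covers the geometric
  substance).
* Dose fields are synthetic sigmoid falloffs for testing the evaluation
  stack; the package does not calculate dose.
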