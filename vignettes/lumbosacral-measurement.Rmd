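---
title: "Automatic lumbosacral parameter measurement: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic lumbosacral parameter measurement: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbometry)
```

## The measurement problem

Sagittal alignment of the lumbosacral spine is quantified on standing
lateral radiographs by a small set of angles and ratios: lumbar lordosis
(LL), the sacral horizontal angle (SHA), the intervertebral space angle
(ISA) of the two caudal discs, and the percentage of lumbar
spondylolisthesis (PLS), a Taillard-style slip ratio.  Manual measurement
is slow and shows substantial inter- and intra-observer variability, which
motivates an automatic pipeline:

1. **segment** the five lumbar vertebral bodies and the sacrum on the
   radiograph (a small multi-scale attention CNN),
2. **locate** ten named vertebral corner points on the segmentation
   (Harris corner detection per connected region),
3. **compute** the four parameters from those landmarks (pure geometry),
4. **evaluate** agreement against reference annotations (Dice, PCK, ICC,
   Pearson r, MD/SD/MAE/RMSE, paired t).

All ten landmarks are endplate corner vertices: `L1SA`/`L1SP` (superior
endplate of L1), `L4IA`/`L4IP` (inferior endplate of L4), all four corners
of L5, and `S1SA`/`S1SP` (superior endplate of S1); `A`/`P` denote the
anterior/posterior vertex.

## Geometric conventions

Coordinates are raster coordinates: `x` = column (rightward), `y` = row
(downward), origin at the top-left pixel centre — the convention of raster
annotation tools.  Angles are computed from direction vectors with the
two-argument arctangent.

* **LL** is the unsigned acute angle between the superior endplate lines
  of L1 and S1, in `[0, 90]` degrees.  **SHA** is the unsigned angle
  between the S1 superior endplate and the image horizontal.  Both are
  reported unsigned because clinical practice reports positive values.
* **ISA** is *signed*: positive when the disc wedge opens anteriorly
  (lordotic), negative for a kyphotic disc.  The sign is defined through
  `anterior_side`, the image side the patient faces, which is either
  supplied or inferred by the landmark stage — never guessed by the
  geometry.
* **PLS** is *signed* (positive = anterolisthesis).  The slip distance N
  is measured **along the lower vertebra's superior endplate line**
  between that line's intersections with the posterior border lines of
  the two vertebrae, and M is the endplate's AP diameter (SA to SP), so
  PLS = N/M x 100.  Measuring N along the endplate (not as a
  perpendicular line distance) matches how the ratio against M is
  defined.
* **Posterior border construction.**  Only L5 carries both posterior
  corners in the vocabulary.  The package uses: L5 — the line through
  `L5SP` and `L5IP`; L4 (no `L4SP`) — the line through `L4IP` parallel to
  the L5 posterior border; S1 (no `S1IP`) — the line through `S1SP`
  perpendicular to the S1 superior endplate.  These are explicit package
  conventions where the underlying definition is not fully determined by
  the ten-point vocabulary.

Two lines are treated as parallel (degenerate intersection) when the sine
of their angle is below 1e-9.  All six parameters are invariant under
translation, uniform scaling and mirroring of the landmarks (with
`anterior_side` flipped), and all but SHA are invariant under rotation —
SHA references the image horizontal by definition.  These invariances are
enforced by property tests at 1e-9.

## The synthetic phantom: a stated world

No public radiograph collection with this annotation scheme exists, so the
package ships a phantom generator that renders five lumbar bodies and a
sacrum as bright convex quadrilaterals on a noisy gradient background.
The generator solves the spine curve so that the *measurement formulas
applied to the generated corners reproduce the requested targets exactly*
(closure to better than 1e-9):

* the S1 superior endplate is set by the SHA target;
* the L5–S1 and L4–L5 disc wedges are set by the ISA targets;
* the wedge remaining to reach LL is spread evenly over the eight
  untargeted segments (five bodies, three untargeted discs);
* slip is imposed by translating a vertebra (and everything above it)
  along the superior endplate of the vertebra below — the same axis along
  which PLS is measured — and the construction keeps each posterior
  border passing through the landmark that defines the zero-slip
  intersection, so the imposed slip equals the measured PLS exactly.

Default targets are drawn from truncated normals with the reference
cohort's means and SDs (LL 49.77 ± 7.82°, SHA 38.09 ± 6.85°, ISA(L4–L5)
14.86 ± 4.07°, ISA(L5–S1) 19.15 ± 8.07°, PLS 12.27 ± 10.31 % and
13.36 ± 9.25 %).  Draws are rejected (up to 100 attempts) when the
residual per-segment wedge leaves `[-3, 8]`° — bodies should stay
near-rectangular — or when the solved spine cannot fit the frame with a
6 px margin.  The default frame is 256 x 128 px at 1 mm/px (portrait
orientation for an upright spine); body widths 26–30 px and heights
16–20 px then correspond to roughly life-size vertebrae.  Intensity is a
vertical background gradient plus per-body plateaus, Gaussian blur
(σ = 1 px) and additive Gaussian noise (SD 0.04).

What the phantom does **not** emulate: bone texture, ribs and iliac
overlap, exposure variation, implants, anatomical variants (transitional
vertebrae), or mis-segmentation structure of real radiographs.  A green
end-to-end test therefore establishes that the pipeline is implemented
correctly and is trainable — not that it meets clinical accuracy on
hospital data.

One raster subtlety: the continuous corner coordinates fall mid-pixel, and
the rasterised mask boundary lies on the half-integer lattice, so a
vertex can sit up to about one pixel diagonal (1.41 px) from the nearest
boundary pixel.  The mask/keypoint consistency test uses that geometric
bound; parameter closure is unaffected because it uses the continuous
corners.

## Segmentation network

The network follows a three-branch multi-scale design: full-, half- and
quarter-resolution branches of 3x3 conv + batch-norm + SiLU blocks, each
with a residual channel-attention block (an SE-ResNet-style unit whose FC
layers are 1x1 convolutions and whose activations are SiLU).  A fusion
module resamples all branches to the quarter scale (average pooling),
concatenates, 1x1-fuses, adds the quarter-scale map and applies a 3x3
conv.  Two parallel heads — a residual dilated-convolution module
(kernels 1/3/5 at dilations 1/2/2, concatenated and 1x1-fused with an
identity shortcut) and a two-block convolutional re-extraction module —
are combined by addition, and a light decoder (nearest-neighbour
upsampling with the full-resolution branch as a skip connection) restores
full resolution before the 1x1 class head.

Because no deep-learning framework is available in the target
environment, the layers are implemented directly (im2col + GEMM
convolutions in C++/Armadillo, batch-norm and SiLU kernels likewise) with
hand-derived backward passes, verified against central finite differences
to a relative error below 1e-5.  Choices the architecture description
leaves open, fixed here as defaults: branch widths 8/16/32 (channel
attention reduction 4), decoder width 16, Dice + cross-entropy loss with
equal weights, Adam with a cosine-decayed learning rate (5e-3 to 2e-4),
batch size 8.  Training is fully seeded; identical configuration and seed
reproduce identical histories and predictions.

Augmentation matches the training recipe of the source pipeline: global
histogram equalisation (probability 0.3), a random intensity gamma in
[0.8, 1.25], and a random rotation in ±5° applied bilinearly to the
image, nearest-neighbour to the mask, and exactly to landmark
coordinates.

The scaled-down validation run (100 phantoms split 8:1:1, 30 epochs,
256 x 128, one CPU) is part of the acceptance suite.  With the default
8/16/32 widths it reached held-out Dice 0.996 (lumbar) / 0.994 (sacrum),
PCK@3 px 98 % and parameter MAE at most 2.9° / 2.8 pp in about 14 CPU
minutes; the acceptance test itself uses slimmer 6/12/24 widths so the
whole test suite stays within its CPU budget on slower machines (the
bounds Dice ≥ 0.90, PCK@3 px ≥ 90 %, MAE ≤ 3 are unchanged).

## Landmark extraction

Connected 8-components per class (area filter 20 px²) must yield exactly
five lumbar bodies and one sacrum — anything else raises an explicit
anatomy-count error rather than a silent guess, because mis-counted
anatomy invalidates every downstream number.  Components are named L1..L5
by centroid row; the sacrum is S1.

Corners are detected on each region's binary support: a 3x3 morphological
opening despeckles the boundary; the support is pre-smoothed (Gaussian,
σ = 1.5 px) before central-difference gradients — without this, the
staircase of a rasterised oblique edge produces spurious positive
responses — and the structure tensor is smoothed at σ = 2 px;
R = det(M) − 0.05 tr(M)².  Candidates must exceed both a relative
threshold (1 % of the maximum) and an absolute floor (4e-5): a digital
disk has a small but strictly positive maximal response at any radius, so
only an absolute floor lets a smooth boundary fail with a corner-shortage
error, as it should.  Greedy non-maximum suppression uses a 5 px radius,
shrunk for small regions.

Localisation is refined in two stages: candidates snap to the support
boundary pixel (within the NMS radius) farthest from the region centroid
— the smoothed response peak sits 1–2 px inside a binary corner — and,
after the four body corners are selected (the 4-subset of up to 12
candidates maximising the enclosed quadrilateral area), each corner is
re-estimated as the intersection of total-least-squares line fits of its
two adjacent quadrilateral edges on the support boundary.  Edge fits are
rejected if they disagree with the coarse edge direction by more than
15°, or would move a corner more than 3 px.  Worst-case vertex error on
rectangles over rotations ±30° and scales 0.5–2 is below 2 px.

Anatomical naming splits the quadrilateral into its two longer opposite
edges (vertebral bodies are wider than tall) — the one with the superior
midpoint is the superior endplate — rather than splitting the four
corners by row, which fails at tilts near 45° (L5 at steep sacral
slopes).  For the sacrum, the superior endplate pair is the convex-hull
edge of the candidates whose outward normal faces the L5 centroid; this
stays correct when the obtuse anterior-inferior sacral corner is
undetectable or when a steep slope makes a lateral edge more horizontal
than the endplate.  `anterior_side`, unless supplied, is inferred from
the sacral slope: the superior sacral endplate descends toward the
patient's anterior.

## Agreement statistics

* **Dice** 2|A∩B|/(|A|+|B|) and one-vs-rest **pixel accuracy**, per class.
* **PCK**: per-landmark percentage of predicted points within r mm of the
  reference (requires pixel spacing; coordinates live in pixels in all
  files, mm conversion happens only here).
* **Observer reliability**: pooled pairwise percentages at 1–5 mm for any
  set of annotation sessions (inter-observer across raters, intra-observer
  across repeat sessions).
* **Reference standard**: coordinate-wise mean across raters.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measure, from the two-way ANOVA mean squares, with the Shrout–Fleiss
  F-based 95 % CI.  This form is chosen because the comparison is
  absolute model-vs-reference measurement (it is reported alongside MD and
  MAE); a constant bias lowers it while leaving Pearson r unchanged, which
  the tests assert.  Zero total variance raises an undefined-ICC error.
* **Agreement report**: MD is the *signed* mean difference
  (model − reference) with its SD; MAE and RMSE are reported separately;
  the paired two-sided t-test uses α = 0.05; the error distribution is
  summarised by min/Q1/median/Q3/max (type-7 quantiles).  Pearson r on a
  constant vector is reported as NA with a warning rather than silently.

Every statistic is tested against an independent re-computation (explicit
pixel loops for Dice/accuracy, direct formulas for MD/MAE/RMSE/quantiles,
`stats::aov` mean squares for the ICC) at 1e-9.

## Numerical and degenerate-input policy

Coincident endplate vertices, M ≈ 0, parallel posterior/endplate lines,
missing landmarks, wrong component counts, and fewer corner candidates
than a body needs all raise classed conditions
(`lumbometry_degenerate_geometry`, `lumbometry_missing_keypoint`,
`lumbometry_anatomy_count`, `lumbometry_corner_shortage`, ...) that the
CLI maps to exit code 2.  Aborting on anatomy violations is deliberate:
the known failure mode of this class of pipeline is a silently wrong
measurement after a poor segmentation.

## Known limitations

* The phantom world is geometric; network performance on it does not
  transfer to clinical images (no public cohort exists to test against).
* Images with missing, extra or transitional vertebrae, or with
  instrumentation, are out of scope: the anatomy check rejects them.
* PNG/JPEG are not read or written (no codec in the supported
  environment); images travel as 16-bit PGM or minimal DICOM.
* The CNN is CPU-oriented and small; it is a faithful, trainable
  implementation of the architecture, not a performance-tuned clinical
  model.
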