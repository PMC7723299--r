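---
title: "Distance-map segmentation and graph-based cell tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-map segmentation and graph-based cell tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distseg)
```

## The problem

Segmenting touching cell nuclei in microscopy images is hard because the
intensity interface between two touching cells is faint or absent, and
because touching cells are rare in most annotated training sets. Discrete
boundary or border labels give a learner only a handful of positive
pixels, all of which move when an annotator draws a cell one pixel larger
or smaller. `distseg` implements a segmentation-by-regression alternative:
two continuous label maps are derived from every instance mask, a network
regresses both, and a seeded watershed converts the predicted maps back
into instances. Objects are then linked through time with a coupled
minimum-cost-flow matcher that models appearance, disappearance and
division explicitly.

## Label transforms

For a label image with cells $C_1, \dots, C_k$:

* **Cell distance.** For each cell independently — all other cells are
  treated as background — every cell pixel receives its Euclidean
  distance to the nearest non-cell pixel, divided by the maximum over the
  cell. Values are in $[0,1]$, peak at 1 in the interior, and are 0 on
  the background. Each cell carries its own normalization, so large and
  small cells contribute equally.
* **Neighbor distance.** For each cell, the cell itself and the
  background are turned into foreground and the *other* cells into
  background; the distance transform of that image, restricted to the
  cell, measures how far each cell pixel is from the nearest other cell.
  The restriction is normalized by its per-cell maximum and inverted, the
  per-cell results are assembled into one map, a grayscale closing
  bridges the thin background gap between close cells, and the map is
  raised to the third power. The result highlights inter-cell interfaces
  — including interfaces to *close but not touching* cells, which is what
  lets a learner extract border-like information from images with few
  actually touching cells.

The per-cell maximum as the normalization denominator is a deliberate
reading of "normalize to $[0,1]$": it is the only one under which the
inversion suppresses the map for cells without close neighbors (a far
neighbor gives ratios near 1 everywhere, hence inverted values near 0),
and under which a cell whose restriction holds a single value inverts to
0. Cells with no other cell in the image are set to 0 directly. The
closing uses a disk (sphere in 3D) of radius 2 px by default; the radius
and the exponent are configurable through `neighbor_distance_config()`.

The continuous maps are also more robust to annotation inconsistencies
than discrete borders: eroding one cell and dilating its neighbor by one
pixel relocates every border pixel, but only perturbs the distance maps
smoothly. The test suite asserts this as a strict inequality of mean
absolute differences on randomly generated pairs of substantially
touching cells.

## Network contract

The prediction model is a U-Net-style encoder–decoder with a single
shared encoder and **two decoder heads**, one per map. Downsampling uses
3×3 convolutions with stride 2 (no max pooling); every hidden
convolution is followed by batch normalization and a rectified linear
unit; both heads end in a linear 1×1 convolution; zero padding keeps
feature-map sizes aligned for the skip concatenations. Feature maps
double per level from 64 to a cap of 1024 at depth 5 (`network_spec()`).

The implementation is plain R built on im2col/GEMM convolutions with full
backpropagation and an Adam optimizer, which makes the whole contract —
forward shapes, loss, schedule, augmentation — executable and testable at
desk scale. Training uses the summed smooth-L1 (Huber, transition 1,
mean reduction) loss over both heads, batch size 8, initial learning
rate $8\times10^{-4}$ decayed by 0.25 after 12 stale validation epochs
down to $6\times10^{-5}$, early stopping after 28 stale epochs or 200
epochs (`training_config()`, `plateau_schedule()`). Augmentation applies
flip (p = 0.75, each axis with half that probability), scale, rotation,
contrast, blur and noise (p = 0.3 each) in that order; geometric
transforms act on image and targets jointly, photometric ones on the
image only. Magnitudes are not dictated by the architecture and default
to scale 0.85–1.15, rotation ±45°, contrast gain 0.7–1.3, blur σ up to
1.5 px, noise σ up to 0.05.

Inputs are min–max normalized to $[-1, 1]$ per frame (per volume in 3D);
constant inputs map to zero. The training smoke test in the suite runs a
narrow configuration (base 8 feature maps, depth 3 — identical layer
structure, fewer channels) on 32 synthetic 64×64 images for 20 epochs
and requires the held-out loss to at least halve; full-size training is
intentionally out of scope, and every downstream component accepts a
*perfect-prediction* stub computed from ground truth instead of a
trained model.

## Watershed post-processing

Both predicted maps are smoothed with a Gaussian (σ = 1.5 px per image
axis, 0.5 across planes in 3D; reflect boundary handling). The region to
flood is `cell > 0.09` (strict), seeds are connected components of
`cell - neighbor^2 > 0.5` (strict) with components under 3 px removed,
and a seeded watershed floods the negated smoothed cell distance inside
the mask (face connectivity; deterministic tie-breaking by flooding
order). All thresholds live in `postprocess_config()`.

In 3D, prediction is slice-wise, post-processing volumetric. Objects
larger than 4/3 of the mean object volume can be re-split by raising the
seed threshold in 0.05 steps (cap 0.95) inside the object until a second
seed appears, then flooding locally. The 4/3 factor is exposed as
`split_volume_factor`; the threshold step and cap are equally
configurable, as no canonical values exist.

Raising the seed threshold can only shrink or split components and
raising the mask threshold can only shrink the mask, so both monotonicity
properties are asserted in the tests. With the neighbor map identically
zero, seeding degrades to pure cell-distance thresholding.

## Tracking

Tracking walks the sequence forward. Each track keeps a rectangular ROI
(150 px per axis in 2D by default; 100 px, or 60 px for very large
volumes, would be typical per-axis choices in 3D) centered on its last
position. Movement is estimated by phase correlation between the raw
image crops at $t$ and $t+1$; the correlation peak, wrapped to signed
shifts, predicts the next position $\hat p = p + d$. Matching costs are
Euclidean distances between $\hat p$ and candidate centroids; a division
candidate pair costs the distance from $\hat p$ to the daughters'
midpoint when the three-clause division gate holds — daughter size ratio
above α = 0.5, combined size below β = 1.2 of the parent, separation
below γ = $2 V^{1/D}$ — and a prohibitive ρ (ten times the
disappearance cost) otherwise. Appearance costs 0; disappearance costs
the longest ROI edge. Tracks without a mask for up to Δt = 3 frames stay
active, so a re-appearing cell can be re-linked across an occlusion.

The per-step assignment is the exact optimum of the coupled flow
problem: every active track takes exactly one decision (match,
disappear, or split into a pair), every object is consumed at most once,
and leftover objects appear as new tracks. The solver is a depth-first
branch-and-bound with an admissible per-track lower bound; tests compare
its optimum against exhaustive enumeration on hundreds of random
instances, including geometry-derived costs. Ties between equal-cost
optima resolve to the lexicographically first decision sequence, so
results are reproducible. Object "position" is the per-axis median of
mask pixels and "size" the pixel count — consistent with the ROI
initialization; after a match the ROI re-centers on the object, after a
miss it dead-reckons with the estimated shift.

Post-processing replicates the last mask at linearly interpolated,
rounded positions across re-linked gaps (never overwriting real masks,
clipped at image borders), and deletes length-one tracks with neither
parent nor children.

## File conventions and evaluation

Masks travel as one 16-bit TIFF per frame (`mask000.tif`, …; zero-padded
0-based indices, pad width at least 3), lineages as text files with one
`L B E P` line per track (label, first frame, last frame, parent or 0).
`seg_measure()` implements the Jaccard-based SEG score: a result object
matches a ground-truth object only if it covers strictly more than half
of it, and SEG averages the Jaccard index over all ground-truth objects,
counting unmatched ones as 0. The combined benchmark scores
$0.5\,(\mathrm{DET}+\mathrm{SEG})$ and $0.5\,(\mathrm{SEG}+\mathrm{TRA})$
are provided by `op_measures()` for externally computed DET/TRA values;
those graph-matching measures themselves are the province of the
official challenge tool and are deliberately not reimplemented.

## The synthetic generator, and what it does not show

`generate_frame()` renders elliptical cells with analytic pixel-center
inequalities: semi-axes 6–11 × 5–8 px (nuclei of roughly 12–22 px
diameter, typical of cultured-cell recordings), 5–25 cells on a 192×192
frame, a target fraction of 0.4 of cells placed as touching pairs
(realized within ±0.15), foreground/background means 0.7/0.1, Gaussian
blur σ = 1 and additive noise σ = 0.04. `generate_sequence()` adds a
global drift (1, 1) px/frame, a per-cell random walk (σ = 0.7 px),
scheduled or random divisions, and transient occlusions. Cells interact
as slightly compressible ellipses: overlaps relax by symmetric pushes
along the center line, which keeps touching interfaces without
interpenetration. At division the parent is replaced by two daughters of
40% of its area each — post-mitotic daughter nuclei are smaller than the
G2/M mother — placed symmetrically along a random axis so that they just
touch. The benchmark tracking scenario fixes 10 cells at the larger end
of the size range (semi-axes 8–11 × 6–8 px) over 20 frames with two
divisions and one three-frame occlusion, so that daughters stay in the
size regime the distance post-processing targets.

What passing tests on this generator do **not** show: performance on
real microscopy (no trained network is evaluated; perfect-prediction
stubs bypass the learning problem), robustness to non-elliptical
morphologies, intensity inhomogeneity, or annotation noise beyond the
single-pixel erosion/dilation family. The generator exists to make the
*pipeline* — label transforms, post-processing, matching, I/O —
verifiable end to end, not to emulate photorealistic data.

## Numerical choices and degenerate inputs

* Distance transforms use the exact separable lower-envelope algorithm in
  any dimension; pixels beyond the frame do not exist, so cells touching
  the frame edge take distances from in-frame background only.
  Anisotropic voxel spacing is ignored (none of the file formats carries
  it).
* Boundary/border adjacency uses 8-connectivity in 2D (26 in 3D);
  out-of-frame pixels induce no boundary.
* Watershed flooding uses face connectivity and a stable priority queue,
  so plateau ties break by insertion order, deterministically.
* Strict inequalities everywhere a threshold is printed as strict:
  mask, seeds, SEG majority rule.
* An empty label image is valid everywhere and yields all-zero maps, an
  empty segmentation, or an empty track set; a constant image normalizes
  to zeros; a constant patch yields a zero shift with a warning.
* Problem sizes in the tests (64–192 px frames, 20-frame sequences,
  narrow network) are the package's chosen desk scale; every algorithmic
  path that runs at this scale is the same code that would run on larger
  data.

## Known limitations

* Division detection inherits the cost structure of the matcher: with
  appearance at cost 0, a split must be cheaper than matching one
  daughter and letting the other appear. When segmentation inflates
  daughter masks so that their combined size exceeds β times the parent,
  the gate correctly refuses, and the division is recorded as a match
  plus a new track. This is the documented behavior of the gate, not an
  error path.
* The re-split of merged 3D objects depends on a second seed emerging
  below the threshold cap; genuinely unimodal objects are kept and the
  event is logged.
* The pure-R network trains comfortably at desk scale only; it is a
  contract implementation, not a GPU training framework.
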