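---
title: "Separating paw bones by joint-space detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating paw bones by joint-space detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A murine hindpaw or forepaw packs 30–33 small bones into a few millimetres:
chains of phalanges and metatarsals/metacarpals, plus a cluster of tightly
apposed tarsals or carpals. In micro-CT at 17.5 µm isotropic resolution,
mineralized bone sits at high Hounsfield values while the joint spaces
between articulating bones are thin (one to a few voxels) low-density
sheets. Segmenting each bone as its own label is the bottleneck for
bone-level biomarkers of inflammatory-erosive arthritis: manual contouring
does not scale, and naive thresholding merges bones wherever the joint
space is lost to noise, partial volume, or — in diseased animals — real
joint fusion.

`pawseg` implements an automated separation pipeline around a single idea:
**detect the peri-articular negative space (the joint space) explicitly,
subtract it from the bone mask to obtain one eroded seed per bone, and let
a marker-based watershed grow the seeds back to the bone borders.** Joint
detection combines a classical enhancement chain with an optional trainable
3D U-Net predictor, and an evaluation module audits the result per bone
(correct / over-split / over-connected / missing).

## The pipeline

Given a calibrated volume (HU):

1. **Bone mask** — closed HU window, default 2500–20000 (`window_mask()`).
   Both boundaries are inclusive; the printed range gives no inclusivity, and
   a closed interval is the deterministic choice.
2. **Black top-hat** (`black_top_hat()`) — grayscale closing minus image,
   cubic structuring element of half-size 3 (≈ the widest joint gap at
   17.5 µm). Responds exactly where dark structures thinner than the element
   sit inside brighter surroundings, i.e. at joint gaps and sharp bone
   interstices. The element is cropped at volume borders.
3. **Sheetness** (`sheetness()`) — multi-scale Hessian analysis (σ ∈ {1, 1.5,
   2} voxels, γ-normalized by σ²). A dark plate in bright surround has one
   dominant *positive* eigenvalue; the score is a Frangi-form product of a
   plate-vs-tube ratio (|λ₂|/|λ₃|, α = 0.5), a plate-vs-blob ratio
   (√|λ₁λ₂|/|λ₃|, β = 0.5) and a structureness term, with the structureness
   scale set to half the per-scale maximum Frobenius norm. This
   parameterization is standard for plate enhancement and is exposed through
   arguments so variants can be swapped.
4. **Tensor voting** (`tensor_voting()`) — the sheetness map is sparsified
   (Otsu) into tokens; each token's plate normal is estimated from the local
   Hessian of the smoothed saliency; closed-form stick votes with the
   classical arc-length/curvature decay are accumulated into a symmetric
   tensor field, whose eigen-gap λ₁ − λ₂ is the output saliency. Voting
   propagates orientation across holes in the membrane, closing gaps that
   single-voxel detectors miss. λ₂ − λ₃ ("surface-ness") is available via
   `saliency_out = "surface"`; plate saliency is the default.
5. **Combination** (`combine_responses()`) — each response (plus the DL
   probability if present) is binarized at its threshold (per-volume Otsu by
   default, 0.5 for the DL probability) and the *union* is taken, then
   dilated with half-kernel 2 (cube; ball selectable). Union is the most
   permissive composition: the dominant failure mode is *missed* joint space
   (which over-connects bones), so any single detector should be allowed to
   close a gap. Serial alternatives can be built from the exported stages.
6. **Markers** (`make_markers()`) — connected components (26-connectivity)
   of bone-mask-minus-joint-mask, discarding seeds below 27 voxels (3³).
   This is the "eroded version of each individual bone".
7. **Watershed** (`watershed_separate()`) — priority-flood restricted to the
   bone mask, topography = negated Euclidean distance to background by
   default (robust to intra-bone texture; inverted intensity selectable).
   Ties break toward the lower marker id, then insertion order, making the
   flood fully deterministic and oracle-testable. The "expansion to bone
   borders" of the original semi-automated recipe is realized as the bone-mask restriction
   of the flood itself.

`run_pipeline()` chains these and logs per-stage voxel counts and timings;
`run_batch()` applies the chain to a directory, isolating per-file failures.

## The joint-space U-Net

`derive_joint_truth()` turns gold-standard bone labels into training targets:
voxels where the half-kernel-5 dilations of two *different* labels intersect,
restricted to background plus bone-boundary voxels, then grown by the same
dilation (thickness and lateral extent). The voxel-level definition of a
"label interface" is open; the
intersection-of-dilations form is symmetric and orientation-free, and is
verified against a brute-force oracle. A flag restricts the interface to
pure background.

The network (`build_unet()`) is an encoder–decoder with skip connections;
encoder stages follow the ResNet-18 pattern — two 2-convolution residual
blocks per resolution level — in 3D, with channel width doubling per level
and strided convolutions between levels. Every convolution except the
single-channel sigmoid head is followed by instance normalization and ReLU.
The normalization deserves a note: with plain conv+ReLU blocks, Dice
training on class-imbalanced patches reliably collapsed into a saturated
all-positive prediction (the sigmoid head's gradients vanish and the net
never recovers — observed across learning rates 1e-4…1e-3). Instance
normalization occupies the batch-norm slot of the ResNet pattern (batch
size is one here) and removes the attractor; the backward pass is verified
by finite-difference gradient checks.

Training (`train_unet()`) follows the canonical protocol: Dice loss, IoU as
the validation metric, Adam at initial learning rate 1e-4, random
initialization, 25% randomized validation split of subvolumes, random
96³ patches from 200³ subvolumes placed on the dense cluster, the distal
extreme, and background (`extract_training_tiles()`). Half the patches are
forced to contain at least one joint voxel (the sampling scheme is a free
parameter). The full-scale protocol is 500 epochs on GPU; the package
default is a desk-scale 50, and the tests use smaller widths/patches still —
explicitly, never silently. Gradients can be averaged over `batch_size`
patches per step; single-patch steps are noticeably noisier.

Inference (`predict_tiled()`) partitions a volume into non-overlapping 352³
tiles (edge-padded, padding cropped from the output) and stitches the
per-tile probabilities; overlapping configurations average. Large tiles use
a direct C++ convolution (the im2col/GEMM path used in training would need
a ~9 GB unfolded matrix at 352³).

## The evaluation module

`match_labels()` tabulates all truth/prediction overlaps. For a truth bone,
*covering* predictions overlap ≥ 50% of its volume (`overlap_min`,
configurable; visual inspection, which this module automates, has no
numeric criterion); *matched* predictions additionally have that bone as their
plurality truth partner. `classify_outcomes()` then applies the error
taxonomy:

* no covering prediction → **missing** (completely eroded bone);
* ≥ 2 matched predictions → **over_split** (one bone as 2+ materials);
* a covering prediction shared with another truth bone → **over_connected**
  (2+ bones as one material);
* otherwise **correct**.

One subtlety: a merged prediction can be plurality-owned by only one of the
bones it swallows, so the "sharing" test must use coverage, not matching —
otherwise over-connection would be unobservable. Fully eroded bones carry
no truth voxels; `segmentation_report()` takes the expected id set from the
`bone_table()` so they surface as missing, mirroring an inspector who knows
the expected anatomy. Anatomically fused structures (e.g. NAVLATINT-type
fusions) are represented as a single table id, which changes the per-paw
denominator exactly as intended.

`accuracy()` is the audit statistic: TP + TN over all outcomes × 100,
with TP = correct bones, FP = over-split, FN = over-connected, and TN ≡ 0
(background is not quantified). Missing bones count as false negatives by
default (a flag
reproduces the strict variant that counts only the two error types). `compartment_summary()` applies the same
formula within anatomical compartments (tarsals/carpals, metatarsals/
metacarpals, proximal/distal phalanges, sesamoids).

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a deterministic synthetic paw: five digit
chains of three capsule bones plus a packed cluster of seven randomly
oriented ellipsoids — 22 bones — with 35 µm (2 voxel) joint gaps, bone at
8000 HU on a 0 HU background, Gaussian partial-volume blur (σ = 8 µm) and
additive Gaussian noise (SD 300 HU), at 17.5 µm spacing. Intensities and
gap scale sit inside the method's HU window and gap regime; rasterization
is exact, so the ground-truth labels are exact.

Primitive sizes are chosen so the phantom sits in the method's intended
*scale regime*: real paw bones are tens of voxels across, so the joint
mask's half-kernel-2 dilation erodes marker seeds by only a thin shell.
Desk-scale bones must be large enough (capsule radius 5, ellipsoid
semi-axes 6.5–8 voxels) that the eroded cores still clear the 27-voxel
seed filter; smaller primitives would make the phantom unrepresentatively
hard in a way real data is not.

Pathology operators mirror the failure modes of diseased paws:
`apply_fusion()` bridges a joint gap at bone intensity while keeping truth
labels distinct — so a detected merge is countable as an over-connection,
the error mode that dominates in arthritic animals; `apply_erosion()`
carves a bone surface-first in both image and truth, and at fraction 1
deletes it (a "missing" bone).

What the phantom does **not** emulate: real anatomy (primitives are convex
capsules/ellipsoids), trabecular microstructure, soft tissue, scanner
physics (beam hardening, ring artifacts), or the forepaw's extra anatomy
(spine/ribs in the field of view). A green phantom test therefore
establishes that the algorithmic chain is implemented correctly and behaves
as designed in the intended regime — not that study-scale accuracy numbers
would be reproduced on real datasets.

For the deep-learning tests the phantom is given extra empty space
(`shape = c(64, 150, 100)`) so the derived joint truth covers only ~20% of
the volume; on the default dense layout an all-positive prediction would
already score IoU ≈ 0.7, making any IoU criterion vacuous.

## Numerical choices and degenerate inputs

* HU window boundaries inclusive; Otsu thresholds take the middle of the
  arg-max plateau (histogram gaps otherwise bias the threshold to the gap's
  lower edge).
* Sheetness returns zero for (near-)flat volumes: derivative kernels cancel
  only to rounding error, so a small absolute structureness floor (1e-6) is
  required before scoring.
* Tensor votes are cut off at 3σ_v (decay < e⁻⁹ ≈ 1e-4 beyond); votes are
  cast only within 45° of the token's tangent plane, per the classical
  stick kernel.
* Watershed determinism: (priority, marker id, insertion order) ordering.
  On equal-priority plateaus the lower id can claim a 1-voxel surface shell
  of a neighbouring basin; bones are disjoint bone-mask components in
  practice, so this only matters inside fused pairs.
* Dice uses an additive smoothing term of 1 (guards the empty-mask case, on
  which a warning is also raised); IoU of two empty masks is defined as 1.
* Instance-norm variance is floored at 0 before the ε = 1e-5 shift;
  constant channels normalize to the learned shift β.
* All randomness (phantom, splits, patch sampling, weight init) flows
  through explicit seeds; `with_seed()` restores the caller's RNG state, so
  a fixed seed gives bitwise-identical phantoms, splits, and label volumes.

## Known limitations

* The classical chain's thresholds are per-volume Otsu; pathological
  intensity distributions (e.g. a volume that is mostly metal artifact)
  would need explicit thresholds via `pipeline_config()`.
* The watershed never creates or merges seeds; errors in the joint mask
  propagate directly (a covered bone core → missing; an unclosed gap →
  over-connection). This is by design — it makes the error taxonomy
  interpretable — but it means the pipeline is only as good as the joint
  detector.
* The U-Net here is a faithful but small re-implementation; nothing in the
  package attempts to reproduce externally trained weights, and training at
  full scale (96³ patches, 500 epochs) is possible but slow on CPU.
* DICOM support covers uncompressed little-endian single-frame CT series
  only; proprietary `.am` stacks are out of scope (NIfTI is the canonical
  interchange format).
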