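---
title: "Detecting very small orchard pests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting very small orchard pests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Citrus psyllids are the insect vector of citrus Huanglongbing; finding them
early is the main lever for controlling the disease. A psyllid is about
2.5 mm long — a handful of pixels even in a 4,000 x 5,000 high-definition
frame — grey, and easily confused with stems, stumps and withered leaves.
Off-the-shelf detectors struggle for three compounding reasons: most field
images contain very few labelled insects (few positive training samples),
naive downscaling of high-resolution frames destroys the targets entirely,
and the background is full of target-lookalikes that random ROI sampling
rarely forces the model to confront.

`psyllidet` implements a complete desk-scale pipeline addressing all three:
constrained copy-paste target enhancement, resolution-preserving
preprocessing, an attention-augmented parallel-resolution detector with
cascaded heads and hard-example mining, and average-precision evaluation. A
synthetic scene generator stands in for field data so that every stage is
exercisable and testable without downloads or a GPU.

## Constrained copy-paste enhancement

The enhancement step increases the number of targets per image by copying
existing sample patches to new positions. Placement is governed by two
overlap rates computed at pixel granularity. With a candidate copy box of
area $\mathrm{Area}_{copy}$, a segmentation mask splitting the frame into an
inner region (leaves, trunk) and an outer region (removed background), and
$n$ existing samples of total area
$\mathrm{Area}_{Samples}=\sum_{i=1}^{n}\mathrm{Sample}_i$:

$$U_{outer} = \frac{|\,\mathrm{copy} \cap \mathrm{outer}\,|}{\mathrm{Area}_{outer}},
\qquad
U_{samples} = \frac{|\,\mathrm{copy} \cap \bigcup_i \mathrm{Sample}_i\,|}{\mathrm{Area}_{Samples}},$$

and a location is accepted only when

$$U_{outer} = 0 \quad\text{and}\quad U_{samples} = 0,$$

i.e. the pasted patch must lie entirely on the foreground and must not touch
any existing target. Both rates are enforced exactly (integer pixel counts,
no tolerance), because the constraint is stated as equality with zero and a
single shared pixel already corrupts either the pasted patch or an existing
annotation.

Design choices that the constraint itself does not fix:

* **The sample set grows cumulatively.** Each accepted paste joins the
  "existing samples" for subsequent pastes; otherwise pasted copies could
  stack on one another even though each is disjoint from the originals.
* **Pasted boxes must lie fully inside the frame.** Partial off-image pastes
  have no meaningful annotation.
* **Placement search is seeded rejection sampling**, uniform over valid
  top-left positions, with `max_attempts = 100` per paste. A guaranteed
  failure (inner region smaller than the patch) is reported distinctly from
  exhaustion of the random budget.
* **Paste count**: by default images are topped up to a minimum of 10
  targets (`min_targets`), or an explicit `copies_per_image` can be given.
* **Harmonisation**: field practice adjusts pasted-patch colour by hand so
  the patch blends in. An automatic substitute (matching the patch's
  mean/sd intensity to its destination neighbourhood) is available behind
  `harmonize = TRUE`, default off; it is not equivalent to manual editing
  and is documented as such.

Segmentation is a pluggable interface, not a trained network: any function
producing a binary mask can be supplied, a stored mask always wins, and the
default is a deterministic colour rule (excess-green index for vegetation,
a bright-brown rule for trunk). This keeps the module fully testable;
fixture scenes carry exact ground-truth masks.

After enhancement, `offline_resample()` duplicates the image set (factor 2
by default). The duplicates are not redundant because per-record stochastic
preprocessing — scale choice and rotation — later differentiates them.

## Preprocessing

High-resolution frames are cropped into **nine blocks** (a uniform 3 x 3
grid; non-divisible dimensions put the remainder into the last row/column)
so that small targets survive at network input size. Boxes crossing tile
borders are clipped and kept only if at least `keep_fraction` (default 0.5)
of their area remains — the alternative of keeping every sliver would
create near-empty positives, and dropping every cut box would waste
annotations near borders.

Multiscale training uses two scales, `(1500, 1000)` and `(1333, 800)`,
chosen uniformly at random per record. Each pair is read in the standard
(long-side cap, short-side target) convention: resize so the short side
hits the target unless the long side would exceed the cap, in which case
the long side is set to the cap. Aspect ratio is always preserved and boxes
scale by the same factor.

Rotation is applied with probability 0.5, with the angle drawn from
\{90°, 180°, 270°\}. Restricting to right angles keeps axis-aligned boxes
exact under the remap — arbitrary angles would require instance masks to
re-derive correct boxes. The remap is verified in tests by painting a box,
rotating the raster and reading the bounding rectangle back.

## The detector

The feature extractor follows the parallel-resolution design: four branches
at 1/4, 1/8, 1/16 and 1/32 of input resolution, exchanged and fused at
every stage so the high-resolution representation — where a 10-px insect
still exists — is never lost. Channel + spatial attention blocks (sigmoid
gated, reduction 16, spatial kernel 7) are inserted at five sites: after
each of the two stem convolutions (stage-1 extraction locks onto target
features early) and on the full-resolution fused output of each of stages
2–4. The stage-fusion placement is one reading of a schematic architecture
diagram; the package pins it down and audits it structurally
(`count_attention_blocks()` must return 5).

Each branch then passes through an atrous spatial pyramid pooling module
whose dilation rates form a "sawtooth" `(1, 2, 5)`: strictly increasing,
with consecutive rates coprime. Large uniform rates such as `(2, 4, 8)`
sample the input on a sparse lattice (the gridding artifact) and can skip a
tiny target altogether; the validator rejects them. Each module runs one
3 x 3 dilated path per rate plus a 1 x 1 path in parallel, concatenates and
projects. A feature-pyramid network fuses the four processed branches
top-down (bias-free 1 x 1 laterals, 2x nearest upsampling, elementwise sum,
3 x 3 output smoothing).

Detection uses three cascaded heads trained at increasing IoU thresholds
(0.5, 0.6, 0.7 — the canonical cascade settings; the source architecture
does not state them) with stage losses combined as

$$L_{total} = 1\cdot L_1 + 0.5\cdot L_2 + 0.25\cdot L_3.$$

ROI sampling replaces random selection with **online hard-example mining**:
per stage, per-ROI losses are sorted and the top 64 positives and top 192
negatives are kept. "ROI loss" is defined here as classification loss plus,
for positives, box-regression loss; negatives rank on classification loss
alone. Ties break by stable index. The sampler is pure and testable in
isolation (`ohem_sample()`), and is cross-checked against a brute-force
extraction oracle.

### Desk-scale training design

R has no deep-learning framework in this package's dependency footprint, so
the tensor machinery (im2col convolution, attention, pyramid modules) is
implemented directly on numeric arrays. Training at desk scale updates the
linear components analytically — the RPN objectness scorer and each stage's
softmax classifier and box regressor — over pyramid features treated as a
fixed multi-scale random-projection feature extractor; convolutional
weights keep their (seeded) initialisation. This is sufficient for the
package's training contract (the weighted total loss must fall on fixture
scenes, which it does, typically from ~1.1 to ~0.4 within 200 iterations)
and keeps a 200-iteration run on 16 scenes of 128 x 128 px within a couple
of minutes on one CPU. It is *not* a claim that full end-to-end training is
reproduced; accuracy-level results on field data are out of scope.

Further training-side choices: anchors are single-scale squares per pyramid
level starting at 8 px (targets are tens of pixels; large default anchors
would never match), proposals are the top-64 anchors by objectness plus the
ground-truth boxes, and ROI features are average-pooled from the pyramid
level whose anchor size matches the box.

## Evaluation

Average precision integrates precision over recall,
$AP = \int_0^1 P\,\mathrm{d}R$, and mAP averages AP over classes,
$mAP = \frac{1}{|C|}\sum_{c\in C} AP(c)$. Because the definition is an
integral, the implementation uses all-point (continuous) interpolation of
the precision envelope rather than 11- or 101-point sampling. Matching is
greedy in descending score order at IoU 0.5 by default (the evaluation
threshold is not stated by the source experiments; 0.5 is the conventional
choice). Score ties break by stable input order. A class with zero ground
truths has *undefined* AP: it is flagged and excluded from the mAP mean
with a warning, never silently counted as zero.

## The synthetic scene generator

Field imagery for this problem is not publicly deposited, so the generator
produces scenes with the same statistical structure: a textured grey
background; an irregular green foreground (union of random ellipses) whose
mask is recorded exactly; small dark elliptical targets placed only on the
foreground — psyllid-like at 4–12 px and fly-like at 8–24 px on the default
512 x 512 scene, preserving the 2.5 mm vs 5 mm relative size and the
small-target regime at test-friendly resolution; and unannotated distractor
blobs in target-like colours, the stems-and-dead-leaves lookalikes that
motivate hard-example mining. Per-image target counts are drawn from
geometric distributions (success probabilities 0.45 and 0.6 for the two
classes), so most scenes carry at most a few targets, mirroring the
sparse-count structure of field data. Pixels are quantised to 8 bits at
generation so PNG round trips are exact, and every scene is deterministic
given its seed.

What the generator does **not** emulate: photorealistic texture,
illumination variation, motion blur, occlusion, perspective, or insects
with realistic morphology. Tests passing on synthetic scenes therefore
demonstrate the pipeline's *mechanics* (constraints honoured, geometry
exact, losses falling, metrics correct), not field accuracy.

## Numerical choices and degenerate inputs

* Boxes are 0-based, half-open on both axes; annotation boxes are integer,
  model-internal boxes may be fractional. COCO `xywh` is the on-disk
  dialect; integer conversion is lossless.
* Pixel-dimension rounding after resize uses round-half-up, so a 666.5-px
  side becomes 667.
* Overlap rates with a zero denominator (no outer region; no existing
  samples) are reported as 0 with an explicit flag.
* The sawtooth validator and cascade/scale/backbone configuration
  constructors fail fast with descriptive errors rather than at forward
  time.
* All stochastic operations (placement search, scale choice, rotation,
  scene synthesis, training) take explicit seeds and restore the caller's
  RNG state.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data: random-geometry oracles on
20 x 20 and 32 x 32 grids (hundreds to a thousand cases), fixture scenes of
64–256 px, one full 4,000 x 5,000 tiling check, 10,000-draw frequency
checks for rotation, and a 200-iteration smoke training run on sixteen
128 x 128 scenes. These sizes were chosen so the whole pipeline, including
training, exercises on a single CPU in minutes.

## Known limitations

* Training updates only the linear detector components (see above); the
  convolutional trunk is a fixed seeded feature extractor.
* The default threshold segmenter is a colour heuristic; real deployments
  should supply masks from a proper segmentation model via the pluggable
  interface.
* Evaluation covers AP/mAP at a single IoU threshold; COCO-style
  mAP@[.5:.95], per-size breakdowns and calibration are out of scope.
* Tiling is a training-time operation; overlapping sliding-window inference
  with detection merging is not implemented.
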