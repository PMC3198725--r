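---
title: "Methods: automated synapse detection in 3D EM volumes"
author: "emsynapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated synapse detection in 3D EM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Asymmetric (presumed excitatory) synapses appear in stained serial EM
volumes of cortex as electron-dense sheets — the pre- and post-synaptic
densities apposed across a narrow cleft — with a cluster of vesicles on
the presynaptic side. Counting and segmenting them by hand across
hundreds of slices is slow and error-prone, and synapses whose cleft
plane lies at a low angle to the imaging plane are easy to miss in
slice-by-slice inspection. With nearly isotropic voxels (FIB/SEM
milling at ~9 nm against 5 nm pixels), the volume can be treated as a
single 3D image and the detection problem attacked with fully 3D
geometric features, which makes the result orientation-independent by
construction.

`emsynapse` implements the full pipeline: a 38-channel 3D feature bank,
a random-forest voxel classifier trained from sparse brush-stroke
labels, deterministic post-processing of the synapse probability map
into segmented candidates, a ball-overlap evaluation protocol, a
seeded synthetic scene generator for testing, and an HTML proofreading
report.

## Voxel features

Every voxel is described by 38 channels computed at multiple Gaussian
scales $\sigma$ (in voxel units, identical on all axes):

| filter | scales $\sigma$ | channels |
|---|---|---|
| Hessian eigenvalues (sorted) | 1, 1.6, 3.5, 5 | 3 each |
| structure-tensor eigenvalues (sorted) | 1, 1.6, 3.5, 5 | 3 each |
| Gaussian-smoothed intensity | 0.7, 1, 1.6, 3.5, 5 | 1 each |
| gradient magnitude | 1.6, 3.5, 5 | 1 each |
| Laplacian | 1.6, 3.5, 5 | 1 each |
| difference of Gaussians | 1.6, 3.5, 5 | 1 each |

Two derived-scale rules are fixed: the difference of Gaussians
subtracts the smoothing at $0.66\,\sigma$ from the one at $\sigma$,
and the structure tensor takes the gradient at the inner scale
$\sigma/2$ before integrating the outer product at $\sigma$. We read
the listed scale as the outer (integration) scale because inner <
outer is the standard convention. Eigenvalues are sorted descending by
signed value, not magnitude, to keep channel semantics stable; the
structure tensor is positive semidefinite, and tiny negative
eigenvalues from floating-point round-off are clamped to zero.

Numerical choices: all convolutions are separable with reflective
boundary extension and kernels truncated at $4\sigma$ (mass loss below
$10^{-4}$). Discrete kernels are renormalized so that polynomial
inputs give their analytic responses at interior voxels — smoothing
kernels sum to one, first-derivative kernels give exactly 1 on a unit
ramp, second-derivative kernels give exactly 2 on $x^2$. This makes
the analytic oracle tests exact rather than approximate. Responses
within one kernel reach of a volume face are affected by reflection;
`compute_feature_stack()` warns when a volume is smaller than
$4\sigma_{\max}+1$ in any dimension.

Raw intensities enter the filters unnormalized; the forest is
invariant to monotone per-channel transforms, and EM stacks do not
come with a calibrated intensity scale.

## Classification

A random forest (default 100 trees, `mtry` $=\lfloor\sqrt{38}\rfloor$)
is trained on the feature vectors of the labelled voxels. Three
classes — synapse, membrane, rest — work better than a binary setup
because membranes are the hardest negatives; the class count is
user-defined. Probabilities are tree-vote fractions, so they sum to
one per voxel exactly. Training is deterministic given the data and
the seed. Duplicate identical labels (likely under brush strokes) are
deduplicated; the same voxel labelled with two classes is an error
rather than a silent corruption.

For volumes that do not fit in memory as a 38-channel stack,
`predict_blockwise()` computes features per block with a halo wide
enough that block-interior responses are exact — note the structure
tensor is a two-stage cascade, so its reach is $4\sigma + 4\sigma/2 =
6\sigma$, not $4\sigma$ — and predicts only block interiors. Blockwise
and whole-volume prediction therefore agree to numerical tolerance
(and in practice bit-exactly, since forest votes are step functions).
`train_on_volume()` uses the same mechanism to compute features only
in patches around the labelled voxels.

## Post-processing

The synapse-class probability map is smoothed with a Gaussian of 5
voxels to suppress voxel-wise noise, then thresholded: connected
components (26-connectivity by default) of voxels with smoothed
probability strictly greater than the core threshold (default 0.98)
and at least 1000 voxels (about the volume of two vesicles at
5×5×9 nm; `suggest_min_size()` rescales this at other resolutions)
become synaptic *cores*. Cores underestimate the true synapse extent,
so each is grown by hysteresis: the segment is the set of voxels with
probability ≥ 0.5 reachable from the core. Boundary semantics are
deliberate: strict `>` at the core threshold ("greater than a given
threshold"), inclusive `≥` at 0.5 ("relax … to 0.5").

Growth is transitive (a flood fill), not a single one-ring dilation: a
one-ring rule cannot recover a full synapse from a small core, and the
hysteresis formulation nests cleanly (raising the relax threshold
shrinks segments monotonically). Where two cores' grown regions meet,
contested voxels go to the core with the nearest core voxel
(Euclidean, ties to the lower id) — colliding segments are not a
situation the post-processing chain otherwise defines. The size filter
applies to the core, before growth, since filtering happens at the
thresholding stage; the reported candidate size is the grown segment.
An optional maximum core size can remove the giant components caused
by myelinated membranes. A ratio-thresholding mode
(`threshold_mode = "ratio"`, thresholding
$p_\text{syn}/\max_k p_k$ rescaled to $[0,1)$) is available behind a
flag but is not the default; the default thresholds the synapse-class
probability itself.

## Evaluation protocol

Gold-standard annotations are balls (center + radius in voxel units).
Before matching, balls touching the left ($x=0$) or top ($y=0$) image
border or the last slice, and balls centered in the first slice, are
excluded — these are the regions where boundary effects degrade the
features. A ball and a candidate overlap when at least one segment
voxel lies within the ball radius of its center (inclusive; any
overlap counts). Matching is sequential with removal: candidates in
descending size order each claim their nearest-centroid overlapping
unclaimed ball, and both leave the pool. Unmatched candidates are
false positives, unclaimed balls false negatives; recall is
tp / gold count and precision tp / candidate count. With zero
candidates precision is reported as 1.0 with an explicit
`precision_defined = FALSE` flag so PR curves stay plottable. The
iteration order and tie-breaks (size-descending, nearest centroid,
lower index) are our determinism choices; the protocol itself does
not fix them. Candidate/ball pairs whose centroids lie within twice
the ball radius without overlapping are flagged as near misses for
manual review, mirroring the manual re-verification step used with
human annotations.

## Synthetic scenes

`generate_scene()` builds seeded EM-like volumes with known ground
truth, so every stage is testable without data downloads. Appearance
follows the morphology the detection problem is defined by: dark is
stained, background bright (≈200 on an 8-bit-like scale, sd 8);
Voronoi cell boundaries form 1–2 voxel membranes (≈90); each synapse
is a pair of dark density discs (≈60; thickness 3–5 voxels, radius
8–15, drawn per synapse) apposed across a ~2-voxel cleft, embedded in
a coplanar membrane patch, with 3–10 vesicle-like spheres (radius 2–3,
≈70) offset to one side; mitochondria are dark-rimmed ellipsoids with
sinusoidal internal striations; optional myelin-like triple sheets
(≈40) reproduce the classic false-positive source; Gaussian noise
(sd 10) is added last. One gold ball per synapse sits at the disc
centroid with the disc radius. Synapse orientations are controlled: a
configurable fraction get axis-aligned normals, the rest uniformly
random oblique ones.

Two design points deserve a note. First, synapses carry their own
coplanar membrane patch at a controlled orientation instead of being
draped onto a Voronoi facet: orientation must be an independent
variable for the orientation-invariance check, which facet geometry
cannot provide. Second, modelling the synaptic density as a pre/post
pair rather than a single sheet follows the morphological criteria
(both densities plus a visible cleft) and gives the synaptic complex a
realistic ~9–12 voxel total thickness. This matters quantitatively:
smoothing a probability map with a 5-voxel Gaussian caps the peak
value a thin sheet can reach (a single 4-voxel sheet cannot exceed
≈0.3), so the detectable operating range of the threshold sweep is a
direct consequence of the complex thickness. Even so, the smallest
planted synapses (radius ≈8) sit near the detection floor implied by
the 5-voxel smoothing and the 1000-voxel size filter — exactly the
size regime the minimum-size filter is designed to reject — so a few
misses at the small end are expected and the recovery benchmark
targets recall at the best point of the threshold sweep, not 1.0.

`make_training_labels()` emulates interactive labelling with short
single-slice strokes: synapse strokes inside the density sheets,
membrane strokes on membranes, and rest strokes alternating between
plain background and distractor interiors (so the forest sees
mitochondria and myelin as "rest", as an annotator would label them).
The labelled fraction stays far below 1% of the volume.

What the generator does *not* emulate: real EM texture statistics
(cytoplasmic granularity, endoplasmic reticulum, microtubules),
imaging artifacts, staining gradients, or the full size and shape
variety of real synapses. Passing the synthetic benchmarks therefore
demonstrates that the pipeline machinery is correct and
orientation-independent, not that a particular precision/recall will
transfer to any real dataset.

## Desk-scale benchmarks

`synthetic_recovery_benchmark()` is the end-to-end check: a
128×256×256 scene with 20 synapses at mixed orientations and default
distractors, 30 brush strokes (10 per class), blockwise prediction in
128³ blocks, a threshold sweep over {0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
0.6, 0.7, 0.8, 0.9, 0.95, 0.98} — dense where the synthetic curves
have their knee — and ball-overlap evaluation at the best-F1 point.
The sweep extends well below the threshold a saturated real-data
probability map would use because the synthetic probability maps peak
lower (see above); the best operating point is picked from the curve,
which is how the threshold is chosen in practice too.

`orientation_invariance_check()` separates the orientation question
from size marginality: it pools axis-aligned vs oblique recall over
scenes whose synapses have matched radii (10–14) above the detection
floor, ≥ 20 synapses in total, and reports the recall gap. Problem
sizes (one 8.4M-voxel scene, two 2.5M-voxel orientation scenes, 100
trees) are chosen so the whole benchmark runs in minutes on one CPU
core while still exercising the blockwise path on a volume much
larger than a block.

## Known limitations

- The forest's operating point on real data depends on labels and
  tissue; the defaults here are standard, not transferred from any
  specific real-data fit.
- Ball radii are isotropic in voxel units; converting annotations
  recorded in nanometres (or anisotropic units) is the user's
  responsibility.
- TIFF float output is 32-bit (a limitation of the TIFF format as
  written here); HDF5 round-trips doubles exactly.
- The matching protocol is greedy-sequential by design, matching the
  removal semantics of the evaluation it implements; it is not a
  maximum bipartite matching, though the two coincide unless overlap
  patterns are many-to-many.
- Very large volumes are bounded by the blockwise path's per-block
  memory (a 128³ block with halo needs ~1.4 GB for its feature
  stack), not by total volume size.
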