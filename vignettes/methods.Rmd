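---
title: "Whole-heart and great-vessel segmentation by skeleton graph matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-heart and great-vessel segmentation by skeleton graph matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdseg)
```

## The problem

Congenital heart disease (CHD) rearranges the connections between the heart
and its great vessels: the aorta (Ao) can arise from the right ventricle
(transposition), a single common trunk can replace both arterial roots,
pulmonary branches can loop behind the trachea (sling), and anomalous veins
can drain into either atrium. Voxel-wise segmentation networks handle the
four chambers and the myocardium well — their shape varies comparatively
little — but they routinely mislabel great vessels in CHD because the
*connection topology*, not local appearance, determines what a vessel is.

`chdseg` implements a hybrid pipeline: learned (or oracle) segmentation
stages produce a low-resolution chamber/myocardium map and a high-resolution
blood-pool map; deterministic geometry then takes over — boundary
refinement, multi-scale smoothing, homotopic thinning to centerline graphs,
and earth mover's distance (EMD) matching of those graphs against a library
of anatomical connection templates, with region growing mopping up whatever
the smoothing erased.

The seven output structures are LV, RV, LA, RA, myocardium (Myo), Ao and PA
(codes 1-7). Two labelling conventions are inherited from how CHD
ground truth is usually drawn: the vena cavae carry the RA code and the
pulmonary veins the LA code, and an anomalous vessel is ultimately coded as
the structure it connects to.

## Pipeline stages and their parameters

### RoI cropping and chamber segmentation

The input volume is resampled to a coarse 64^3 grid on which a binary
foreground segmentation is produced; the tight bounding box plus a margin
(default 8 coarse voxels) maps back to full resolution as the region of
interest. The RoI is resampled to 64^3 and segmented into the four chambers
plus Myo. At that resolution boundary detail is necessarily lost — which is
why the next stage exists.

Every learned stage accepts a pluggable backend. The *oracle* backend
answers from an attached ground-truth volume (majority-vote downsampling
for the 3D stage, with background losing ties; in-slice 8-neighbour
boundary extraction for the 2D stage). It makes the downstream geometry
testable in isolation and is the reference point for the trained backends.
One subtlety: the oracle target of the 3D stage is the *chamber bodies* —
an anomalous vein that the final truth codes as RA is deliberately not part
of the 3D target, otherwise it would be claimed as chamber and could never
reach the graph stage that is supposed to classify it. The phantom
generator exposes this as `body_truth` alongside `truth`.

### Boundary refinement

The high-resolution blood pool (chambers + vessels, myocardium excluded) is
the boundary information the 64^3 stage lost. Upsampled chamber labels are
first intersected with the pool (chambers are blood pool by definition);
the remaining pool is then grown into by `K = 5` rounds of simultaneous
6-connected competitive dilation — ties go to the label with more adjacent
claimed voxels, then the lowest code. Bounding the growth at `K` keeps
tube-like vessels out of the chambers; everything still unclaimed is the
vessel-only pool handed to the graph stage. `K` is exposed because phantom
and clinical voxel scales differ.

Low-resolution foreground that the pool rejects can only be muscle, so it
joins the Myo mask before the chamber subtraction; Myo is never re-segmented
at high resolution, and its boundary fidelity is bounded by the 64^3 stage —
on phantoms this is the dominant residual error (raising mean Myo Dice
above ~0.9 at a 1.5x upsampling factor would require exactly the
high-resolution muscle segmentation the pipeline deliberately omits).

### Multi-scale smoothing

Touching vessels — or vessels joined by thin spurious bridges from imperfect
blood-pool segmentation — must separate into their own graphs for matching
to work. The pool is therefore smoothed at scales `k = 1..7`: the indicator
is convolved `k` times with an all-ones 3x3x3 kernel and the accumulated
field binarized at the majority of its total mass (`14 * 27^(k-1)`, i.e.
14-of-27 at `k = 1`). Binarizing *after* the iterated convolution is the
design choice that matters: thresholding after every round is nearly
idempotent (a structure either dies immediately or persists at all scales),
whereas the iterated kernel widens with `k`, so half-spaces survive every
scale while necks thinner than about `k` voxels melt away — giving genuinely
different candidate topologies per scale. The `k = 1` threshold (default 14,
the majority) is exposed.

### Skeletonization and graphs

Each smoothed mask is reduced to a one-voxel-thick curve skeleton by
homotopic thinning with (26, 6) connectivity: a border voxel may be deleted
only if it is *simple* (object restricted to its 26-neighbourhood has one
26-component, and the background restricted to the 18-neighbourhood has one
6-component touching the centre face-wise) and not an endpoint. Deletion
proceeds in increasing order of the Euclidean distance transform, with local
occupancy as tie-break, so the skeleton rides the medial ridge and endpoints
stay centred — a solid cylinder thins to its axis. Component count is
preserved by construction.

Skeleton voxels with 26-neighbour count different from 2 are graph nodes;
maximal degree-2 chains become edges, resampled every 2 mm of arc length.
Every sample carries `r`, the inscribed-sphere radius, read from the
distance transform of the *unsmoothed* pool — smoothing distorts calibre,
and `r` should reflect the true vessel. Pure cycles are anchored at their
lexicographically smallest voxel and become self-loops. Graphs that repeat
across scales (same node/edge counts, node positions within a voxel) are
deduplicated, keeping the smallest `k`.

### EMD matching

A graph becomes a weighted point distribution: one bin per edge sample,
weight `r^3` (the blood-pool volume around the sample), Euclidean ground
distance. Weights are normalized to total mass 1 — raw `r^3` masses are
generally unequal between candidate and template, and classical EMD is only
defined for balanced mass — and coordinates are mapped to a normalized
frame (weighted centroid, weighted RMS scale), making the match invariant
to position and global size while preserving shape and topology cues. The
EMD itself is an exact min-cost-flow (successive shortest augmenting paths
with potentials); it is a metric on these distributions and is
cross-checked against an independent linear-program solver in the tests.

The template library holds one entry per anomaly family. Each template is
built by running the non-learned half of the pipeline on the *canonical*
(unjittered) phantom anatomy of that family, so templates live in exactly
the representation candidates arrive in — truncated vessel roots,
distance-transform radii. Every template sample carries its vessel category
(Ao / PA / anomalous, the explicit third category for anomalous vessels);
vessel roots and tips are recorded as key points with a connection list.
Candidate x template pairs are scored exhaustively; the minimum-EMD pair
wins (ties: smaller scale, then lower template id). Multi-component
candidate graphs are scored as single distributions rather than matching
components separately — the simpler of the two readings of per-vessel
matching, and the one that needs no component-template assignment step.

### Label transfer and region growing

Vessel-pool voxels surviving the chosen smoothing scale take the category
of the nearest edge sample (majority per edge over nearest template
samples). Anomalous components are re-coded to the chamber they touch
(most adjacent voxels; nearest chamber if detached) — the "coded by its
connections" convention. Voxels the smoothing erased are absorbed by
26-connected competitive growth from the labelled voxels; components no
front can reach are reported as unresolved rather than silently labelled.

## The training stages

The trained backends are small native U-nets (conv + instance norm + ReLU
blocks, max-pool encoder, nearest-upsample decoder with skip concatenation,
1x1 output conv) written against an internal im2col/GEMM convolution engine.
The loss is the combined soft-Dice + cross-entropy
\[
L = \Big(1 - \frac1C \sum_j
  \frac{2\sum_i p_i^j g_i^j}{\sum_i (p_i^j + g_i^j)}\Big)
  + \frac{1}{NC} \sum_j \sum_i -g_i^j \log p_i^j ,
\]
with a smoothing constant of 1e-6 on each Dice ratio so absent classes
contribute a ratio of 1, probabilities clamped to `[1e-7, 1]` before the
log, and natural logarithms (any base only rescales the CE term). The
learning rate is 0.0002 for the first half of the epochs and 0.00002
afterwards, with Adam; all initialization and data order is seeded.

Several choices make that schedule productive at desk scale, where Adam
moves each parameter by roughly the learning rate per step and total
displacement is the binding constraint at 2e-4. Inputs carry a positional
encoding — normalized coordinates and their squares — so axis-aligned
quadric boundaries (the phantom chambers) are linearly representable and
equal-intensity chambers are separable by position. The output layer reads
the decoder features concatenated with the raw inputs (an input-to-output
skip) and applies a fixed logit gain of 25, so confident softmax outputs
are reachable with small weight displacement. 3D training runs on the 8^3
sub-blocks of the tightly cropped 64^3 RoI rather than the full volume —
512 optimizer steps per epoch at the same compute — and trained-backend
inference tiles the volume with the same block size so instance-norm
statistics match training exactly. Adam uses `beta2 = 0.99` (the variance
estimate adapts within tens of steps, suiting short runs). One numerical
subtlety matters for stability: the cross-entropy part of the loss gradient
is taken directly in its closed logit form `(p - g)/(NC)`; routing the
clamped `-g/p` derivative through the softmax jacobian instead would vanish
for classes whose probability has collapsed and leave them permanently
dead. 2D training uses whole slices with a 3x3x1 kernel and in-plane
pooling in the same engine.

## The phantom generator

The generator emulates the *topological* variety of a CHD CT dataset, not
its radiometry: chambers are axis-aligned ellipsoids, the myocardium a 3 mm
shell around the ventricles, vessels are tubes swept along spline
centerlines with tapering radii (aortic root 5 mm, pulmonary 4.5 mm — small
pediatric-scale calibres), at 1 mm isotropic voxels on a 96^3 grid (a
desk-scale stand-in for clinical 512 x 512 x 130-340 CTA). Intensities are
three-tissue (blood pool 300, myocardium 150, background 0) with seeded
Gaussian noise (sigma 20). Label precedence where shapes overlap is
chambers > vessels > myocardium, which keeps the blood pool continuous at
the valve planes. Five anomaly families are generated: normal, swapped
origins (transposition-like), common trunk, anomalous vein draining to RA,
and a hooked pulmonary sling. The suite generator cycles round-robin
through the families and jitters centres (±2 mm), semi-axes (±1 mm),
control points (±1.5 mm) and radii (±10%).

What passing tests on phantoms does *not* show: robustness to CT physics
(beam hardening, motion, partial volume beyond linear blur), to
non-ellipsoidal chamber shape, to contrast heterogeneity inside the blood
pool, or to anatomies outside the five encoded families. The phantom suite
demonstrates that the geometric half of the pipeline — refinement,
skeletonization, matching, growing — recovers connection topology when the
segmentation stages do their job; it cannot certify the trained stages on
clinical data.

## Numerical choices and degenerate inputs

* Dice of two empty voxel sets is 1.0 (structure correctly absent, flagged
  in reports) — relevant for CHD cases genuinely lacking a structure.
* Voxel geometry is 0-based `(x, y, z)` with column-major arrays; volumes
  carry per-axis spacing in mm and NIfTI round-trips preserve it.
* Empty masks: skeletonizing an empty mask returns an empty skeleton; an
  empty vessel pool (or one erased at every scale) raises a
  "vessel pool vanished" error that the pipeline propagates by stage name.
* All tie-breaks are deterministic: lowest label code in competitive
  growth, smallest scale then lowest template id in matching, first
  category in edge votes, lexicographically smallest anchor in cycles.
* Distributions with all-zero radii are rejected as degenerate rather than
  normalized into NaNs; EMD refuses unnormalized inputs.
* The paired t test reports a zero-variance pairing as an error rather
  than an infinite statistic.

## Problem sizes

The shipped tests and the acceptance script run the pipeline on 96^3
phantoms (the 20-case suite, oracle backends), train the 2D smoke net on a
few 48 x 48 slices, and overfit the 3D smoke net (2 levels, 8 initial
filters, 100 epochs) on one 64^3 RoI; those sizes keep every stage's
behaviour visible while a full run stays in the minutes range on a laptop
CPU.

## Known limitations

* The template library covers the five phantom families; a clinical
  library (14+ CHD types with sub-variants) is a data-curation exercise on
  top of `write_graph_library()`, not a code change.
* Whole-candidate matching can be fooled when one component of a
  multi-vessel graph matches well and the other poorly; per-component
  matching with assignment is the documented alternative.
* Myocardium accuracy is bounded by the low-resolution stage (see above).
* The EMD solver is exact but dense O(n^2) per Dijkstra; graphs are
  hundreds of bins here. For much denser graphs an entropic approximation
  would be the standard substitute.
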