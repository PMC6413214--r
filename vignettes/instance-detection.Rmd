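---
title: "Bottom-up pig instance detection: representation, decoding, evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up pig instance detection: representation, decoding, evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigparts)
```

## The problem

Monitoring group-housed pigs from a top-down camera requires detecting every
animal in the pen together with its orientation. Pigs lie against each other,
so region-proposal detectors that assume separable bounding boxes fail
exactly where monitoring matters most. `pigparts` takes the bottom-up route:
detect body parts everywhere in the image first, then group them into whole
animals.

Each animal is represented by four landmarks on the back surface: left ear
$l$, right ear $r$, shoulder $s$ and tail $t$, where "shoulder" and "tail"
are points on the centre ridge of the back. Shoulder and tail are always
annotated; ears only when visible. The pair $(s, t)$ fixes both the location
and the heading of the animal.

## The 16-channel image-space representation

A frame with $N$ animals is encoded into 16 image-space channels
(`encode_frame()`):

* **Channels 1–4, part heatmaps.** Each annotated part of animal $n$ is a
  symmetric 2D Gaussian kernel with standard deviation $\sigma_n$, scaled so
  its centre equals 1.0. Overlapping kernels in the same channel combine by
  pointwise maximum, so the fixed unit peak survives clutter and a single
  detection threshold works at every animal size.
* **Channels 5–16, association vector fields.** For the three part pairs
  $l \leftrightarrow s$, $r \leftrightarrow s$, $s \leftrightarrow t$ and
  both directions, a channel pair stores the constant pixel offset
  (source minus target) inside a disc around the source part. Sampling the
  pair at a detected part and subtracting points at its partner.

The kernel width adapts to animal size:
$\sigma_n = 0.16\,(\mu_{s\to t} + \delta_{s\to t,n})$, where
$\delta_{s\to t,n}$ is the shoulder-tail distance of animal $n$ and
$\mu_{s\to t}$ the frame mean. Blending the individual length with the frame
mean keeps a curled-up animal from shrinking its kernel to nothing. The
association discs cover the region where the source kernel exceeds
magnitude 0.2, i.e. radius $\sigma_n\sqrt{-2\ln 0.2}\approx 1.794\,\sigma_n$.
Where same-channel discs of different animals intersect, the stored vector
is the kernel-magnitude-weighted average of the contributors (normalised to
sum to one); with more than two contributors the same normalised weighting
applies. An explicit binary assignment mask records which association pixels
are defined — a legitimate zero offset component would otherwise be
indistinguishable from "unassigned", and the training loss needs the
distinction bit-exactly.

Rendering truncates kernels at $4\sigma$ (dropped values are below
$3.4\times10^{-4}$, far under any decoder threshold).

Degenerate annotations with shoulder equal to tail are accepted by the I/O
layer, because they can occur in raw files, but rejected with an explicit
error by `compute_sigma()`: a zero-length body defines neither a kernel
scale nor an orientation.

## Decoding maps into instances

`decode_maps()` converts any 16-channel map — ground-truth encoding or
network output — into discrete instances:

1. **Smoothing.** All channels pass a normalised 5×5 box filter (replicate
   padding). This is a no-op on constants and interior affine ramps but
   suppresses pixel noise in network outputs before maximum detection.
2. **Regional maxima.** A pixel is a part detection when it is $\ge$ every
   value in its 15×15 neighbourhood (clipped at borders) and $\ge$ the
   detection threshold (default 0.25). A connected plateau of tied maxima
   yields exactly one detection, at its lexicographically smallest
   $(y, x)$ pixel — one detection per physical peak.
3. **Sub-pixel refinement.** Independently per axis, a parabola through the
   three samples at offsets $\{-1, 0, +1\}$ moves the coordinate to the
   vertex $\delta = (v_- - v_+)/(2(v_- - 2v_0 + v_+))$. Refinement is
   skipped when the peak touches the border, when the curvature is
   non-negative (no local maximum — the vertex would be meaningless), or
   when $|\delta| > 0.5$ (overshoot). Refinement happens before association
   sampling, and the association channels are sampled bilinearly at the
   refined real-valued coordinates, so grouping uses the best coordinates
   available.
4. **Association distances.** For parts $p, q$ the distance is the mean of
   the two prediction errors
   $d(p_n, q_m) = \tfrac12(\|(p\to q)_n - q_m\| + \|(q\to p)_m - p_n\|)$.
   The ablation baseline replaces this with the plain Euclidean distance
   between the parts.
5. **Hungarian grouping.** Each of the three distance matrices is solved by
   a minimum-cost bipartite assignment (Jonker–Volgenant shortest
   augmenting paths, implemented in the package; rectangular matrices leave
   the surplus side unmatched). No maximum-distance gate is applied — the
   pipeline deliberately avoids resolution-dependent distance parameters —
   though the evaluation metric below compensates.
6. **Instance formation.** Every matched shoulder–tail pair is an instance;
   ears attach to their assigned shoulder only when that shoulder belongs
   to an instance. Lone parts are discarded. Each instance carries a
   confidence — the minimum peak value among its parts — which is plumbing
   for downstream consumers, not part of the detection criterion.

## Evaluation: cross-check matching

An ungated Hungarian assignment between ground truth and detections will
happily pair far-apart instances to minimise the global cost; a distance
gate would fix that at the price of a resolution-dependent parameter.
`cross_check_match()` instead pairs instance $n$ and detection $m$ only if
each is the other's minimum-cost match under
$\|s_n - \tilde s_m\| + \|t_n - \tilde t_m\|$ (ears excluded: shoulder and
tail alone define a complete instance). Argmin ties break to the lowest
index; a tie that makes mutuality ambiguous resolves to no-match. Counts
micro-average across frames: TP/FP/FN are summed, then precision, recall
and F-measure derive from the sums. Empty-set conventions (precision 1 with
no detections, recall 1 with no ground truth, F 0 when both rates are 0)
let a perfectly empty frame score perfectly.

A caution when interpreting the Euclidean ablation: with equal instance
counts and clean maps, a two-animal cross-pairing produces two swapped
detections that are still mutual nearest neighbours of their ground truths,
so the ungated cross-check counts them as true positives. Precision only
drops when the mis-grouping creates preference conflicts — which is why the
ablation suite (`abutting_suite()`) includes a four-animal pinwheel whose
cyclic cross-pairing does exactly that, alongside the canonical
side-by-side pair that demonstrates the swap itself.

## The hourglass network

`hourglass_spec()` describes the 41-block encoder–decoder: 3×3 convolution
blocks, five 2×2 max-pooling stages (strides 2), five max-unpooling stages
(stride 0.5) that reuse the pooling indices of their paired pools, a depth
concatenation with the same-resolution encoder feature map immediately
after every unpool, and a final 3×3 convolution to 16 channels. Effective
stride is the running product $s^{\text{eff}}_l = s^{\text{eff}}_{l-1}
s_l$; the receptive field follows
$r_l = r_{l-1} + (w_l - 1)\,s^{\text{eff}}_{l-1}$ with $w_l = 3$ for
convolutions and the lower bound $w_l = 1$ for pooling operations. On the
shipped spec the stride peaks at 32 and returns to 1, and the receptive
field is 363 pixels (radius 181) — comfortably larger than the largest
(140 px) animals at the 480-column working scale.

```{r}
spec <- hourglass_spec()
tail(receptive_field(spec), 1)
max(effective_strides(spec))
count_parameters(spec)
```

Published per-block tabulations of this family of architectures pin the
profile at both ends (receptive fields 1, 3, 5, 5, 9 entering the encoder;
359, 361, 363 leaving the decoder; stride 16–32–16 around the bottleneck)
but are not arithmetically consistent in the interior under the recursion
above: every decoder convolution at effective stride $\ge 2$ adds a
multiple of 4 to $r$, so $r$ cannot move from 181 at the first unpool to
359 at a stride-2 block. The shipped spec therefore reproduces the head,
the bottleneck and the tail of the profile exactly — including the final
363 — and places one concatenation after every unpool; block kinds in the
last few positions before the output differ from the tabulated sampling.
Encoder convolution counts per level are (2, 2, 3, 3, 3), which is the
unique integer solution placing the five pools at blocks 4, 7, 11, 15, 19
with $r = 181$ at block 18; the decoder uses (4, 2, 1, 2) plus two
full-resolution convolutions, closing the count at 41 blocks and the
receptive field at 363.

Design choices where the architecture family leaves freedom:

* **Conv block composition.** Convolution + per-channel spatial
  normalisation + ReLU. Normalising over each image's spatial extent
  (instance-style) rather than across a mini-batch keeps behaviour
  identical for any batch size, including 1, and removes train/eval mode
  divergence; the first convolution's bias is consequently a free
  parameter with zero gradient.
* **Channel widths.** Not derivable from the architecture tables; the
  default profile (40, 80, 120, 160, 160) doubles per level, capped at the
  bottleneck, landing at 3.93 million coefficients — the one printed
  constraint being "nearly four million".
* **Loss.** Mean-squared error, selective: part channels contribute at
  every pixel; association channels only where the assignment mask is set,
  each term normalised by its own pixel count. The gradient with respect to
  masked-out association outputs is exactly zero, so the network is free to
  hypothesise vectors where no part exists instead of being dragged to
  zero. Because offsets are measured in pixels, the association term is
  roughly three orders of magnitude larger than the part term at
  initialisation, and in a short CPU-scale run a shared trunk optimised on
  the raw sum learns vectors while the part heatmaps stay at noise level.
  `selective_loss()` therefore takes an `assoc_weight` multiplier on the
  association term: 1 (the default, used everywhere loss semantics are
  tested) is the canonical loss; the training demonstrations use
  $10^{-4}$, which brings the two terms to comparable magnitude at
  initialisation. Grouping a handful of well-separated animals tolerates
  offset errors of several pixels, so detection quality, not offset MSE,
  is the binding constraint at desk scale.
* **Optimisation.** Adam (default learning rate $10^{-3}$), exposed in
  `train_config()` together with epochs, batch size and the augmentation
  spec; the original training protocol is not recoverable from the
  architecture description and is not a claim of this package.

All network primitives (im2col convolution, pooling with indices,
unpooling, the backward passes) are implemented in the package with
RcppArmadillo; gradients are verified against finite differences in the
test suite.

## Augmentation

`augment_pair()` applies left–right flips (probability 0.5), rotations
uniform on $[0°, 360°)$, scalings uniform on $[0.5, 1.5]$ and per-axis
shifts uniform on $\pm 20$ px, jointly to the image and the target. A flip
swaps the left/right ear labels and the corresponding association groups
and mirrors x offset components; rotation rotates stored offset vectors;
scaling multiplies them; shifts leave them unchanged. The rotation
convention is fixed once: positive angles rotate $+x$ towards $+y$
(clockwise on screen with y down).

Two augmentation paths exist. The default training path transforms the
*annotation* and re-encodes, which keeps Gaussian peaks exactly unit-height
(warping rendered maps blurs them). The map-space path warps the rendered
channels (bilinear for heatmaps, nearest for vector/mask channels so
constant regions do not smear across boundaries) and exists to check the
two paths against each other: `consistency_check()` asserts peak positions
and sampled offsets agree within 0.5 px. Instances whose shoulder or tail
leaves the frame are dropped; ears are dropped individually. Photometric
augmentation is deliberately out of scope — spatial transforms cannot mimic
lighting variation, and none is claimed.

## Synthetic scenes

`generate_scene()` renders top-down pens: elongated ellipses with a
brighter head disc and ear nubs on a textured floor, additive Gaussian
noise, optional polygon pen mask with out-of-mask pixels blacked out.
Keypoints derive deterministically from each body pose — tail at the rear
end of the major axis, shoulder at 70% along it, ears flanking the head at
a perpendicular offset of a quarter body length. These placement fractions
are fixture conventions chosen once for plausibility, not measurements of
pigs. Shoulder-to-tail lengths are drawn uniformly from 30–140 px at the
480-column scale, covering the span reported for the real data; a
configurable fraction of animals is placed as parallel, touching
side-by-side pairs. The generator is a pure function of (config, seed).

What the generator does *not* emulate: realistic pelt texture, lighting
variation, IR imagery, occlusion by pen furniture, or animals overlapping
vertically. Tests that pass on these scenes therefore validate the
*geometry* of encoding, decoding, grouping and evaluation, and show the
network can learn the representation — they do not certify performance on
real barn footage.

## Problem sizes in the shipped suites

Chosen so the whole suite exercises every claim at desk scale:

* Round-trip suite: 200 frames at 360×480, 2–12 animals, shoulder-tail
  lengths 30–60 px, same-part separations kept above $2\max\sigma$ so
  kernels cannot interfere, and keypoints at least 8 px from the image
  border so no kernel is truncated by the frame edge (replicate-padded box
  filtering biases the smoothed maximum of a clipped kernel by up to
  ~1.5 px) — the regime in which decoding ground truth must be exact
  (recall = precision = 1, sub-half-pixel localisation).
* Training demonstration: 128-column scenes (about a quarter of the
  working scale, shoulder–tail lengths 10–36 px), 200 training and 50
  held-out frames, a small-width (8, 16, 24, 32, 32) hourglass trained
  for 12 epochs with Adam at $6\times10^{-3}$, batch size 1, association
  weight $10^{-4}$, then decoded at threshold 0.25. This is a property
  check that the full pipeline — generator, encoder, network, decoder,
  metric — learns and detects (recall and precision above 0.9), not a
  reproduction of results on real data.
* Augmentation commutation: 100 random draws on a two-animal frame.

## Known limitations

* Two same-type parts closer than the peak window (15 px) collapse to one
  detection; the representation cannot express coincident parts.
* The Euclidean ablation's failure modes are only partially visible to the
  ungated cross-check metric (see above).
* Training at full 480-column scale with the default width profile is
  computationally out of reach of a single-CPU session; the package trains
  reduced configurations and exposes the full-size spec for completeness.
* `preprocess_image()` resizes bilinearly (the available resize filter);
  sub-pixel differences against other interpolators are far below the
  annotation noise the kernels model.
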