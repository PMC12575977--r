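---
title: "Estimating fish–camera distances from stereo and monocular observation streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fish–camera distances from stereo and monocular observation streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fintrack3d)
```

## The problem and the model

Intrusive objects inside aquaculture net pens repel farmed fish, and the
distance the fish keep is a behavioural signal worth measuring continuously.
A compact stereo camera pair mounted on the object can provide that signal at
video rate, provided one can turn per-frame perception outputs (caudal-fin
detections, segmentation masks, sparse feature matches, or monocular metric
depth maps) into 3D fish positions. `fintrack3d` implements that
transformation and the statistics computed from it. The perception networks
themselves are outside the package: every pipeline consumes their outputs
through a file format or an R function, so a detector can be swapped for a
file replay or for the simulator's oracle without touching pipeline code.

The camera model is a rectified pinhole stereo pair: the right camera is the
left camera displaced by the baseline $b$ (millimeters) along $+x$, pixels
are continuous, 0-based, origin top-left, $y$ down. For a left-image point
$(u, v)$ with right-image horizontal coordinate $x_r$,

$$Z = \frac{b\,f_x}{x_l - x_r}, \qquad
  X = Z\,\frac{u - c_x}{f_x}, \qquad
  Y = Z\,\frac{v - c_y}{f_y},$$

with output converted to meters at exactly one place. The depth formula uses
the *horizontal* focal length: disparity is horizontal, which makes $f_x$ the
only self-consistent reading of the otherwise ambiguous focal length in the
textbook formula. Degenerate disparities ($\le$ `d_min`, default 0.5 px) and
depths beyond `z_max` (default 10 m — beyond any plausible underwater working
range for this rig) are rejected with distinct reason codes rather than
propagated.

## Tracking

`track_sequence()` is a two-stage IOU tracker in the ByteTrack family.
Stage 1 assigns active *and* lost tracks to high-confidence detections
(`conf >= 0.5`) by minimum-cost assignment on $1 - \mathrm{IOU}$, gated at
IOU $\ge$ 0.2; stage 2 lets low-confidence detections (`[0.1, 0.5)`) rescue
only still-active tracks, gated at IOU $\ge$ 0.5. Lost tracks are dropped
after `track_buffer = 30` frames (1.2 s at 25 fps). These values are package
conventions, chosen for reproducibility: the field study that motivates this
package delegated its tracker parameters to a citation without printing
them. There is deliberately no motion model: association is against the last
observed box, which is adequate at 25 fps for fish that move a few pixels
per frame, and keeps the tracker's behaviour fully explainable by its two
thresholds.

Determinism matters more than raw fidelity here: within every frame,
detections are put in a canonical order (decreasing confidence, then
$x, y, w, h$) before association, so the tracker's output is invariant under
permutation of the detection order in the input file — a property the test
suite checks directly.

## Stereo association

Cross-view correspondence is a one-to-one assignment on a $1-\mathrm{IOU}$
cost matrix (masks or boxes), solved by an in-package Hungarian
implementation (the $O(n^3)$ potentials formulation). We implemented the
solver rather than binding an external one because the contract demands a
brute-force oracle check anyway — the test suite verifies it against
exhaustive permutation enumeration on a thousand random matrices — and no
assignment solver is part of the guaranteed dependency stack. Pairs whose
IOU falls below `min_iou = 0.1` are dropped *after* assignment: the
optimiser is otherwise forced to complete near-disjoint pairings, and such
spurious completions are exactly the wrong-fish matches one wants to reject.

Cross-view IOU is computed with **no disparity compensation**, mirroring the
procedure used in the field: with a 42 mm baseline, a fin's disparity is a
fixed fraction (about 0.4 for the default fin size) of its projected width
at *every* range, so same-fish regions always overlap across views. For
wide-baseline rigs, where that would break down, `disparity_shift` can
pre-shift the right-side items; it is off by default and exists as a
documented deviation aid only.

The feature-match pipeline follows the published recipe: keep matches with
confidence strictly above 0.1 that fall inside a tracked box (boundary
counts as inside; a point inside several boxes goes to the nearest box
centre), then estimate the right-image position of the box centre as
`mean(right points) + (box centre − mean(left points))`. Only the horizontal
component enters triangulation; the vertical residual is kept as an
epipolar-consistency diagnostic (warn threshold 5 px, counted in the run
summary), since in a rectified pair it should be zero up to noise.

## The simulator: what it emulates, and what a green test proves

The simulator stands in for field video. It emulates the acquisition
geometry of the motivating rig — 42 mm baseline, 1920×1200 px, 25 fps — and
fish at 0.8–4 m (the observed field ranges were roughly 0.7–3.75 m). The
focal length (1400 px) is a simulator convention giving realistic 15–60 px
disparities; the real rig's calibrated intrinsics were never published. Fish
follow a correlated random walk (Gaussian heading turns of 0.15 rad/frame;
speed a truncated Gaussian around 0.35 m/s ≈ 0.8 body lengths/s for a ~1 kg
salmon; reflection at the volume boundary), and their caudal fins are planar
camera-facing ellipses of 0.05 m half-width with a slow aspect wobble.
Observations are: boxes (ellipse extents with Gaussian corner noise,
Beta(8, 2) confidences, Bernoulli dropout at 5%), oracle masks, match point
pairs sampled on the fin plane (jitter 0.5 px), clutter matches, and a
z-buffer metric depth raster over a constant 8 m background — monocular
depth models characteristically map unbounded backgrounds to a fixed
distance, and the constant reproduces that failure mode. The noise defaults
are package conventions (no field values exist); they are stated once here
and the tests treat them as the fixed world.

Two generator choices deserve emphasis because they define what the
noiseless end-to-end test establishes:

* **Oracle masks carry sub-pixel coordinates.** A mask is a symmetric
  integer lattice attached to the *continuous* ellipse centre, so its
  centroid equals the true projection to floating-point accuracy, while
  rounding the coordinates recovers a dense pixel raster for IOU. A
  conventionally rasterised mask has O(0.1 px) centroid quantisation error —
  millimetres of depth error at 2 m — which would make "recovers truth to
  1e-6 m" unattainable for the mask pipeline by construction rather than by
  any property of the method. Real segmentation masks are integer rasters;
  the package accepts those too, at the corresponding sub-pixel accuracy
  cost.
* **Mask centres are jittered by the pixel-noise parameter.** The renderer
  applies `pixel_noise_sd` to mask centres as well as box corners, modelling
  segmentation boundary noise. Without it the mask pipeline would be exactly
  noise-free at every noise level and the noise-monotonicity property would
  be vacuous for it.

A green noiseless test therefore establishes that the geometry, association,
tracking and bookkeeping are exact — not that any pipeline is accurate on
real imagery, where detector misses, segmentation leakage, occlusion by
conspecifics, turbidity and non-planar fins dominate. The simulator models
none of those beyond dropout and Gaussian localisation noise, renders no
partially-visible (edge-clipped) fins, and its fins never occlude each other
in the mask/box streams (only in the depth raster's z-buffer).

## Evaluation statistics

The behavioural output is the per-frame *closest-fish distance*: the minimum
Euclidean norm of the 3D records in each frame (`--dist z-only` style
Z-coordinate distance is available as an option, since published tables do
not state which convention was used). Case summaries pool the per-frame
minima across replicates and report mean ± sample sd. Pooling at frame level
(rather than averaging replicate means) was chosen because the large
published spreads (e.g. ±0.79 m) are only consistent with frame-level
variation; the replicate-means alternative is available via `agg`.

Accuracy against an independent reference is reported as the mean absolute
error over cases with a Student-t interval,
$\mathrm{MAE} \pm t_{1-\alpha/2,\,n-1}\,\mathrm{sd}(e)/\sqrt{n}$.
This exact rule is *inferred*: it reproduces, to three decimals, all four
published MAE values (0.412, 0.187, 0.205, 0.197 m) and all four 95% CIs
from the published per-case means and the sonar reference column shipped in
`inst/extdata/example_case_distances.csv` — the package's tests assert
this, and no other simple rule (normal quantiles, population sd) does.

Trajectory smoothing is Savitzky–Golay (default window 7, order 2 — our
defaults; the published figures do not state theirs), implemented by local
least squares with the leading/trailing full-window fit evaluated at the
edge positions, so polynomials up to the filter order are reproduced exactly
everywhere including endpoints.

## Numerical and design choices

* Monocular "central pixel" is the floor of the continuous box centre
  (rounding convention unstated in the source; floor is idempotent on
  integer centres). A 3×3 patch-median read exists behind `patch =
  "median3"`.
* Unbalanced assignment matrices are padded with a cost larger than any
  feasible total; padded assignments are discarded.
* Tie-breaks everywhere are deterministic and documented: canonical
  detection order in the tracker, ascending ID in depth rankings, nearest
  box centre in match-to-box association.
* `stats::aggregate`/base data frames throughout; no compiled code — profile
  work showed mask IOU (integer-key intersection) dominates, and it is fast
  enough at the tested scales (~4 s per 3-fish 100-frame scene with all
  three stereo pipelines).
* All randomness flows from one master seed per scene; observation noise
  uses a derived sub-seed so motion and noise can be varied independently.
  RNG state is saved and restored around every generator call.

## Known limitations

* No lens distortion, no calibration estimation: calibration is consumed as
  a validated config file, assumed already rectified.
* Frame pairing assumes hardware-synchronised streams with identical frame
  indices; nothing resembling a software time synchroniser is provided.
* Track identities come from the left camera only; right-side detections are
  anonymous, so stereo record counts are bounded by left-track counts.
* The simulator's fins are fronto-parallel ellipses; oblique fins, whose
  left/right silhouettes genuinely differ, are exactly the hard case the
  box-based pipeline suffers from in the field and are not modelled.
* Real-time concerns (node graphs, message transport, inference latency) are
  out of scope; this is an offline/desk implementation of the methods.
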