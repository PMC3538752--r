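---
title: "Global-search tractography: models, parameters and validation design"
author: "gstract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-search tractography: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deterministic fiber tracking propagates a trajectory through a diffusion
tensor field one local decision at a time.  Small errors accumulate, so
streamline methods struggle with branching, kissing and strongly curved
pathways, and with the low-anisotropy tissue near functional areas and
tumors.  When the task is anatomical connectivity between two known
regions — for instance two language areas localized by functional MRI —
a global formulation is possible: search for the minimum-cost path
between the two regions over the whole tensor field at once.  `gstract`
implements that global search (GS) together with the two deterministic
reference trackers it is usually compared against, a fiber-tract
similarity framework for quantifying their agreement, and a software
phantom simulator that makes every claim testable against ground truth.

## Diffusion tensor model

Each voxel carries a symmetric tensor $D$ estimated from a b0 volume and
at least six diffusion-weighted volumes by log-linear least squares on
$S_k = S_0\exp(-b\,g_k^{\top} D\, g_k)$.  The default acquisition model
is the six-direction oblique double-gradient scheme at
$b = 1000\,\mathrm{s/mm^2}$, a common clinical protocol.  Eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ yield fractional anisotropy

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
  \frac{\lVert \lambda - \bar\lambda \rVert}{\lVert \lambda \rVert},$$

and the Westin shape coefficients
$c_l = (\lambda_1-\lambda_2)/\lambda_1$,
$c_p = (\lambda_2-\lambda_3)/\lambda_1$, $c_s = \lambda_3/\lambda_1$
classify the ellipsoid as linear, planar or spherical (ties resolved in
that order).  Negative fitted eigenvalues — possible under noise with
only six directions — are clamped to zero for FA and shape computation
and flagged.  Tensors are interpolated trilinearly on their six unique
components; eigen-analysis happens after interpolation.  Voxel centers
sit at integer 0-based indices under the voxel-to-world affine, and all
world coordinates are millimetres.

## The three trackers

**Streamline propagation (SP)** integrates the major-eigenvector field
with a fourth-order Runge–Kutta scheme at a fixed 0.5 mm step,
bidirectionally from every seed.  Eigenvector signs are arbitrary, so at
every evaluation (including the four RK stages) the vector is flipped to
keep a non-negative dot product with the incoming direction.

**Tensor deflection (TD)** propagates
$v_{out} = \mathrm{normalize}(\hat D\, v_{in})$ with
$\hat D = D/\lambda_1$: in anisotropic tissue the direction is deflected
toward the major axis, in isotropic tissue it is maintained.

Both trackers seed every voxel whose FA meets the threshold, stop when
FA drops below it, when the trajectory leaves the volume, or after 2000
steps per direction (no angle-based stop), and keep only fibers that
intersect both regions of interest.  Kept fibers are not clipped to the
ROIs.

**Global search (GS)** works on a structured lattice whose spacing is
chosen so that the mean step over the neighbor-offset set equals a
configured average step (default 2 mm).  The default offset set contains
74 directions: all of $\{-2..2\}^3$ minus the origin, minus offsets
collinear with a shorter offset, minus the $(\pm2,\pm2,\pm1)$ class —
the only natural lattice construction that reaches exactly 74.  A finer
98-direction set adds that class back.  Each lattice edge is scored at
its midpoint by

$$\mathrm{cost} = \ell \cdot
  \mathrm{clip}\!\left(1 - \hat p(v)\, d(v)\, \mathrm{FA},\;
  \varepsilon,\; 1\right),$$

where $\ell$ is the segment length, $\hat p(v) = \max(0, (v^{\top}Dv -
\lambda_3)/\lambda_1)$ is the propagation probability with the isotropic
fraction subtracted (zero in every direction on an isotropic tensor, so
isotropy earns no credit), and $d(v)$ is the divergence factor: the
cosine of the angle between $v$ and $e_1$ for linear shapes, and the
cosine of the angle between $v$ and the $e_1$–$e_2$ plane for planar and
spherical shapes, where a single principal direction is ill-defined.
Edges whose midpoint FA falls below the threshold are forbidden, and
transitions between consecutive offsets are restricted to a maximum
bending angle (default 60°).  The floor $\varepsilon = 10^{-3}$ per mm
makes $h(n) = \varepsilon\,\cdot$ (Euclidean distance to the nearest
goal node) an admissible, consistent A* heuristic, so the returned path
cost is exactly the minimum over all feasible paths.  The search state
is the pair (node, arrival offset), which makes the bending constraint
exact.

`reconstructPathway()` emits one minimum-cost path per ROI-A voxel
(start nodes are snapped to the nearest lattice node and qualified on
the FA at the voxel center, which keeps the emitted tract independent of
the lattice density), deduplicates identical node paths, and on global
failure retries once at a fallback threshold.  Because all start nodes
share one goal set and one edge model, those per-start searches are
computed in a single multi-goal sweep over the same state space; the
per-start A* (`astarSearch()`) returns identical costs and is checked
against an exhaustive shortest-path relaxation in the tests.  ROI
padding is never applied to GS.

## The adaptive protocol for deterministic trackers

Where SP/TD fail to connect, the clinical protocol first relaxes the FA
threshold from 0.25 to 0.2 and pads the ROIs by up to 4 voxels, one box
dilation at a time.  The selection rule: the 0.25 tract is used iff it
required no more than two additional paddings compared to the 0.2
tract.  `adaptiveReconstruct()` implements exactly this and records both
padding counts and the chosen branch.

## Similarity framework

Two tracts $F$, $G$ are compared through a relation that pairs every
fiber of $F$ with its closest fiber of $G$ and vice versa, duplicates
excluded — outliers therefore weigh more than they would over all
pairs.  Fiber-to-fiber distance is the mean of closest-point distances
over the duplicate-excluding closest-point relation, again symmetric by
construction.  `s_avg` averages the relation's distances; `s_min` is the
closest pair.  Curvature- or angle-based measures are deliberately
avoided: grid-bound GS fibers would always lose against inherently
smooth streamlines.

Before any metric, grid-bound or irregularly sampled fibers are
resampled to the trackers' 0.5 mm spacing (points stay on the original
polyline; no smoothing), and each fiber pair is trimmed: after orienting
the second fiber to match the first (minimal summed endpoint distance),
the closest point on the other fiber to each endpoint is found at both
ends; if exactly one of the two is an interior point, the protruding
segment beyond it is removed from the fiber carrying it.  Diverging ends
(both interior) are never trimmed, so shared course is preserved and at
most one fiber is trimmed per end.  "Interior" is an exact index test —
resampling makes indices well-defined.  Ties in closest-point and
closest-fiber searches break toward the lower index, so runs are
deterministic.  FA similarity averages trilinearly interpolated FA over
all points of the trimmed fibers participating in the relation,
per tract; points outside the field are excluded and counted.

## The phantom simulator

The simulator is first-class, tested code: it generates centerline
geometry (straight, branching, kissing, spiral), rasterizes a
ground-truth tensor field, simulates the DWI signal, adds Rician noise
$\sqrt{(v + n_1)^2 + n_2^2}$ with $\sigma = S_0/\mathrm{SNR}$ (SNR
defined on the b0 image, matching MR magnitude statistics), and places
end-ROI slabs covering the full tube cross-section.  Voxels inside a
tube get a prolate tensor along the local tangent; overlap regions
average the contributing tensors component-wise, mirroring the
partial-volume averaging that defeats single-tensor trackers at
crossings; the background is isotropic.

Study conditions (chosen once, then frozen):

* 2 mm isotropic voxels, $b = 1000\,\mathrm{s/mm^2}$, six oblique double
  gradients, $S_0 = 1000$; SNR 15 and 30, bracketing what the matching
  clinical protocol delivers.
* bundle eigenvalues $(1.7, 0.3, 0.3)\times10^{-3}\,\mathrm{mm^2/s}$
  (plateau FA $\approx 0.80$), background diffusivity
  $0.7\times10^{-3}$.
* straight / branching / kissing: $64^3$ volumes, 6 mm tube radius —
  thick bundles, like the pyramidal and optic tracts whose character
  they share.  The branching trunk splits into two arms at 40° with a
  smooth 10 mm turn; the kissing configuration is two 30 mm-radius arcs
  touching tangentially.
* spiral: $48\times48\times16$, an inward Archimedean spiral of 3.5
  turns from radius 30 mm to 6 mm with a thin 2 mm tube.  The thin tube
  keeps the anisotropic channel barely resolved at 2 mm voxels, and the
  2.9 mm of background between turns stays below any usable FA
  threshold.  This is the regime in which the three tracker behaviors
  separate: the deterministic trackers terminate within the first cycle
  (their longest fiber from the outer ROI covers about two thirds of
  it), while the global search, free to route around local noise dips,
  traverses the full spiral.  Wider or fatter variants were examined
  during design and rejected: they either let the deterministic trackers
  survive the whole spiral or open partial-volume bridges between turns
  that the search can shortcut across.
* per-phantom FA thresholds are set 0.1 below the mean FA in the core of
  the pathway (voxels within half a tube radius, at least one voxel, of
  a centerline), computed from the noisy fitted field — diffusion
  characteristics differ per phantom, so thresholds are defined
  individually, identically for all methods.

Spiral progress is quantified by the azimuthal sweep around the spiral
axis (the range of the unwrapped polar angle along a fiber), not by
summed segment turning: step-level noise jitter inflates the latter by
tens of degrees per centimetre without any real circling.

What the phantoms do **not** emulate: eddy currents, ghosting, motion,
partial Fourier, susceptibility distortion, or spatially varying noise.
Passing tests on them therefore demonstrates the algorithms' geometric
and statistical behavior under the stated signal model, not robustness
to every artifact of a clinical acquisition.

## Numerical choices

* Tensor fit: closed-form log-linear least squares (not weighted or
  nonlinear) — deterministic and appropriate for a six-direction
  protocol; voxels with non-positive signal get the zero tensor and a
  flag.
* Interpolation domain: the box spanned by the voxel centers; stepping
  outside terminates a tracker and forbids an edge.
* Priority-queue ties in the search break by insertion order, so every
  run is reproducible; all stochastic steps flow from one configured
  seed.
* Trimming refuses any cut that would leave fewer than two points and
  records the refusal.
* Mann–Whitney U (used for group comparisons in the benchmark harness)
  computes exact two-sided p-values by enumerating group assignments up
  to a combined n of 12 — valid under ties, where the standard exact
  routine refuses — and the tie-corrected normal approximation with
  continuity correction beyond; significance level 0.05.

## Problem sizes used by the test-suite and benchmark scripts

The phantom benchmark runs at the full study conditions above.  The
grid-refinement experiment (74- vs 98-offset grids) runs on a
$64\times48\times32$ branching phantom with a 48 mm bundle over five
noise seeds; the finer grid follows its source setup in combining the
98-direction set with a shorter 1.5 mm average step.  Optimality of the
search is verified against exhaustive relaxation on randomized fields up
to $6^3$ nodes, where the full (node, arrival-offset) state space can be
enumerated quickly.

## Known limitations

* Single-tensor model only: no multi-shell, no ODF/HARDI
  reconstruction, although the cost function would accept any
  directional diffusion profile.
* The GS result is grid-bound; sub-voxel smoothness is not a goal, and
  similarity to smooth trackers is bounded below by the lattice spacing.
* At high per-phantom thresholds a severe local noise patch can sever
  the thin spiral tube for every method including GS (observed in
  roughly one noise seed in ten at SNR 30); the benchmark reports
  connection rates rather than a single binary outcome for this reason.
* ROI padding, FA relaxation and the bounding-box mechanism are
  implemented as protocol tools; no claim is made that their clinical
  defaults transfer to other acquisitions unchanged.
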