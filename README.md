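# gstract

Global-search tractography for diffusion tensor imaging (DTI), with the
deterministic reference trackers, a fiber-tract similarity framework, and
a software-phantom simulator for ground-truth validation.

## What it is for

Reconstructing a white-matter pathway between two known regions of
interest — for example two functionally localized language areas — is
hard for standard fiber tracking: streamline methods accumulate local
errors and fail on branching, kissing and strongly curved pathways, and
in the low-anisotropy tissue near functional areas or tumors.  `gstract`
solves the task globally: it searches for minimum-cost paths between the
two ROIs over a structured grid spanning the tensor field, so that all
candidate trajectories compete at once.

The cost of a path segment of length ℓ with unit direction *v* through a
tensor *D* with eigenvalues λ₁ ≥ λ₂ ≥ λ₃ is

    cost = ℓ · clip(1 − p̂(v) · d(v) · FA,  ε, 1)

* `p̂(v) = max(0, (vᵀDv − λ₃)/λ₁)` — the directional propagation
  probability with the isotropic fraction subtracted, so isotropic
  tensors earn no credit;
* `d(v)` — the divergence from the principal diffusion direction:
  |cos∠(v, e₁)| for linear tensor shapes, the cosine of the angle to the
  e₁–e₂ plane for planar/spherical shapes;
* `FA` — fractional anisotropy;
* ε = 10⁻³ keeps the A* heuristic admissible, so returned paths are
  provably minimum-cost.

Edges below an FA threshold are forbidden, adjacent segments respect a
maximum bending angle, and an optional bounding box restricts the search
space.  The package also provides:

* **SP** — 4th-order Runge–Kutta streamline propagation, and **TD** —
  tensor deflection (`v_out ∝ D·v_in`), both with whole-volume seeding,
  ROI filtering and the adaptive FA-relaxation / ROI-padding protocol;
* **tract similarity** — trimmed, duplicate-excluding closest-point
  distances (`s_avg`, `s_min`) plus per-tract FA averages;
* **phantoms** — straight, branching, kissing and spiral bundles as
  ground-truth tensor fields with simulated DWI and Rician noise at a
  chosen SNR.

## Worked example

```r
library(gstract)

spec <- phantomSpec("branching", snr = 30, seed = 42)
pd   <- buildPhantom(spec)
pd
#> PhantomDataset: branching phantom, 64 x 64 x 64 x 7 DWI, SNR 30
#>   ROI sizes 104 / 100 voxels; 2 centerline curve(s)

field <- phantomField(pd)        # tensor fit from the noisy DWI
field
#> TensorField: 64 x 64 x 64 voxels, 2 x 2 x 2 mm
#>   FA range [0.011, 0.959]; 0 flagged voxels

sp <- runTracker(field, pd@roiA, pd@roiB,
                 trackingParams(faThreshold = 0.6), method = "sp")
sp
#> FiberTract: 415 fibers [sp], FA threshold 0.6

gs <- reconstructPathway(field, pd@roiA, pd@roiB,
                         params = gsParams(faThreshold = 0.6, faFallback = 0.6))
gs
#> FiberTract: 64 fibers [gs], FA threshold 0.6

tractSimilarity(gs, sp, field = field)
#> SimilarityReport: s_avg 1.304 mm, s_min 0.439 mm over 464 pairs
#>   mean FA 0.798 / 0.790 (0 points outside field)
```

Both methods recover the branching bundle: the streamline tract and the
global-search tract agree to 1.3 mm on average (the search is
grid-bound, so sub-voxel deviation is expected), the closest fiber pair
lies 0.44 mm apart, and both tracts sample the same anisotropy
(mean FA ≈ 0.79–0.80 against an in-bundle plateau of 0.80).

`runPhantomSuite(suiteConfig())` runs the full benchmark — every phantom
at SNR 15 and 30 with all three methods, connection success, pairwise
similarities and spiral coverage.  A command-line front end for NIfTI
volumes and TrackVis-style streamline files lives at
`inst/scripts/gstract-cli.R` (subcommands `phantom`, `track`, `compare`,
`suite`).

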