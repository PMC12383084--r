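---
title: "Automated aortic 4D flow analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated aortic 4D flow analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind
`aortaflow`: what each processing stage assumes, which parameters matter,
what the synthetic phantom does and does not emulate, and where the design
was genuinely open.

## Pipeline model

A 4D flow acquisition yields a magnitude image series `[X,Y,Z,T]` and a
three-component velocity field `[X,Y,Z,T,3]` encoded against a velocity
limit (VENC, cm/s): measured phase in (-pi, pi] maps linearly to velocity,
so true velocities beyond +/-VENC wrap around (alias). The pipeline runs a
fixed progression per dataset — import, noise masking, background
phase-offset correction, anti-aliasing, segmentation, geometry, and
quantification — with the entry point chosen automatically from the input
(DICOM directory; HDF5 container; HDF5 with segmentation, which skips
preprocessing and segmentation with a logged notice). Jobs come from a CSV
spreadsheet (`Subject ID`, `Data Path`, semicolon-separated `Steps`,
optional `Params` overrides); steps execute in canonical order regardless
of sheet order, failures are isolated per job, and nothing in the chain is
random, so a rerun reproduces every output byte-for-byte. The AI variants
of the preprocessing and segmentation steps are plug-in hooks only: no
trained networks ship with the package, and without a registered plug-in
those keywords fail with "model not available".

## Preprocessing

All thresholds are fixed, pre-defined values exposed in
`preprocess_params()` and echoed into every correction report:

- `noise_threshold = 0.10` — a voxel is noise when its time-averaged
  magnitude falls below this fraction of the maximum time-averaged
  magnitude. Applying the mask zeroes the velocity of noise voxels.
- `static_sd_threshold = 0.05` — a voxel is static tissue when the temporal
  standard deviation of every velocity component stays below this fraction
  of VENC (noise voxels excluded). Static tissue anchors the background
  fit. Slowly moving near-wall blood can satisfy this criterion; the fit is
  robust to such contamination because static voxels vastly outnumber it,
  but exact offset recovery is only guaranteed over truly static tissue.
- `poly_order = 2` — eddy-current-like background offsets are modeled as a
  3D polynomial (in physical mm) fitted by least squares to the
  time-averaged velocity over static voxels, per component, and subtracted
  from all frames. Injected offsets of degree <= order are removed exactly
  (to solver precision); the operation is idempotent. A rank-deficient
  design (e.g. coplanar static voxels) is rejected.
- `alias_iterations = 4` — anti-aliasing works along the temporal axis:
  a sample whose difference to its temporal predecessor exceeds VENC is
  shifted by the multiple of 2*VENC that minimizes the difference, the
  first frame anchoring the sequence. Passes repeat up to the fixed count,
  stopping early once no sample changes; samples whose temporal differences
  never exceed VENC are never touched. Spatial unwrapping is not
  implemented — a voxel aliased in *every* frame (including the first) is
  invisible to a purely temporal scheme. This is a documented limitation.

## Geometry

Segmentation comes from an external mask (NIfTI or the HDF5 container;
grids must match exactly, no resampling) or from a threshold on the PC-MRA
(time-averaged magnitude x speed) at 20% of its maximum — a deliberately
simple, deterministic fallback standing in for learned segmentation. Only
the largest 26-connected component is kept; discarded components raise a
QC flag.

The centerline is a medialness-penalized minimal-cost path through the
voxel adjacency graph of the mask: edge cost is the physical step length
divided by the squared wall distance (chamfer distance transform), so the
cheapest path hugs the medial axis. Endpoints come from a double Dijkstra
sweep (farthest voxel from the deepest voxel, then farthest from that) with
each endpoint re-centered to the deepest voxel among the far candidates.
The path is then re-centered onto per-point cross-section centroids,
extended to the vessel openings along the local tangent, smoothed with a
moving average (window 5), resampled to 1 mm arc steps, and differentiated
centrally for tangents. A skeletonization-based variant was considered and
rejected: no robust 3D thinning is available in the R ecosystem, and for
non-branching vessels the minimal-cost path is equally accurate (straight
tube: axis recovered to well under a voxel; U-tube: length within 0.3% of
the analytic 2L + pi*R_b) while being simpler and deterministic.

Orientation follows the anatomy: the start is the end whose tangent points
superiorly. Both ends of a U-shaped aorta qualify, so ties are broken
toward the anterior limb (smaller first-axis coordinate), matching the
ascending aorta's position in sagittal-oblique chest coverage;
`orientation = "flip"` overrides the heuristic.

Analysis planes sit at arc positions 0, 25, 50, ... mm (normal = local
tangent; count is always `floor(length/spacing) + 1`). Through-plane flow
samples each plane on a grid at the minimum voxel dimension, interpolates
velocity trilinearly, gates samples by nearest-neighbor mask lookup, and
keeps only the in-plane connected lumen region around the plane center —
without that restriction a plane through one limb of a curved vessel also
crosses the other limb, where the opposing flow direction cancels the flux.
Q(t) = sum (v . n) dA in mL/s. Planes at the very vessel openings
under-read because trilinear interpolation there mixes with zero-velocity
background; interior planes of a steady-flow tube agree within a few
percent (partial-volume at openings is inherent to voxelized data).

The AAo/arch/DAo split labels each mask voxel by the segment of its
nearest centerline point; the centerline is segmented by the
superior-inferior tangent component s (s > +0.5 ascending, s < -0.5
descending, else arch), falling back to equal arc-length thirds when either
threshold yields nothing (straight tube). The +/-0.5 rule is a geometric
surrogate for anatomical landmarks: on a circular bend it places the
boundaries R_b * pi/3 of arc beyond the limb-bend junctions, which is
acceptable for regional statistics but is not a landmark detector.

## Quantification

- **Peak velocity** pools voxel speeds over the region and all timeframes
  (the temporal maximum *is* the systolic peak; a config switch restricts
  frames). The spike filter sorts the speeds, takes the top 1% (at least 10
  samples), and scans that segment upward: at the first successive
  difference exceeding 10x the segment's mean difference, the list is
  truncated and everything above discarded. The one-line filter rule
  admits variants, so this exact semantics is frozen and tested against an
  independently coded brute-force oracle.
- **Kinetic energy**: KE(t) = sum 0.5 * rho * dV * |v|^2 with
  rho = 1.06 g/cm^3 = 1060 kg/m^3. The quadratic velocity dependence is
  dimensionally forced. Because the field reports such energies both as
  regional totals and as per-voxel averages, both variants (peak-systolic
  and time-averaged) are emitted under unambiguous column names.
- **Viscous energy loss**: EL(t) = sum mu * Phi * dV with mu = 3.2 cP and
  Phi the incompressible dissipation function. Gradients use central
  differences in physical units, one-sided at region borders with only
  in-region neighbors. Boundary handling materially affects EL: for a
  parabolic profile the one-voxel wall layer carries
  1 - ((R-h)/R)^4 (~40% at R = 8 mm, h = 1 mm) of the dissipation
  integral, so border voxels are *included* by default — against a
  Poiseuille cylinder the rate then matches 2*pi*mu*vmax^2*L within ~1%,
  versus ~35% low when borders are excluded. `boundary = "exclude"`
  remains available as a config flag. EL is emitted as a rate (uW) and as
  the cycle-integrated energy (uJ).
- **Pulse wave velocity**: each flow curve is upsampled to 1 ms and
  restricted to its systolic upslope — the rising edge from the 20%
  crossing of its peak up to the peak, shifted to the 20% baseline and
  zero elsewhere. The reference (first-plane) segment is cross-correlated
  against each downstream segment over lags 0-250 ms (zero-padded,
  fixed-norm, so the argmax equals the normalized correlation's), and the
  integer argmax is refined sub-millisecond by a parabolic fit through the
  three points around the peak. Delays regress on arc position;
  PWV = 1/slope. Slope <= 0 or r^2 < 0.5 flags the result "unreliable PWV"
  with delays retained for QC. Two details were settled empirically
  against analytically constructed, exactly time-shifted curves: linear
  1 ms interpolation and a 20-80% window bias the recovered PWV by 5-8% at
  6.4 m/s with a 40 ms frame spacing — short near-linear windows correlate
  near 1 at many lags, and the flow-onset kink makes local interpolation
  sampling-phase-sensitive. Cubic-spline upsampling with the
  20%-crossing-to-peak window recovers 3, 6.4 and 10 m/s within 1.4%.
  Both window fractions and the lag bound are exposed as arguments.

## The phantom and what it validates

`generate_phantom()` builds a U-shaped tube (ascending limb, half-torus
arch, descending limb; defaults: 60 mm limbs, 30 mm bend radius, 8 mm lumen
radius, ~214 mm centerline) on a 64^3 grid of 2 mm voxels with 20 frames at
40 ms — values representative of clinical thoracic-aorta protocols (voxel
1.5-2.5 mm, frame spacing 30-42 ms, VENC 80-300 cm/s; VENC here 150 cm/s).
Flow is quasi-steady Poiseuille: a parabolic radial profile scaled by a
half-sine systolic waveform over the first third of the cycle, evaluated at
t - s/PWV for arc position s, which imposes the ground-truth wave speed
exactly as a waveform time shift. Defaults: v_peak 1.3 m/s and PWV
6.4 m/s, typical adult values. A static-tissue shell surrounds the lumen;
magnitude is high in the lumen, moderate in the shell, low outside.
Optional degradations: an injected polynomial velocity offset (recorded
coefficients), seeded Gaussian velocity noise (default SD 0.02 m/s, a
realistic noise floor at this VENC), and phase wraps of -2*VENC*sign(v) on
a recorded random fraction of detectable systolic lumen samples. The grid
origin is chosen so voxel centers sample the limb axes exactly, letting the
sampled peak velocity reach v_peak.

Everything the pipeline measures has a closed form on this phantom: KE
integrates to pi*rho*v^2*R^2*L/6 per unit waveform, EL to 2*pi*mu*v^2*L,
flow curves are exact time-shifted copies, and the wrapped-sample set is
known. What the phantom does **not** emulate: MR physics (k-space,
partial-volume averaging, phase noise correlated with magnitude),
Womersley (unsteady) velocity profiles, wave attenuation and reflection,
branching vessels, valve jets and turbulence. Passing tests therefore
demonstrate correctness of the numerics and the processing contracts, not
clinical accuracy on pathological flow.

A steady `poiseuille_cylinder()` (default 1 mm voxels) provides the
analytic KE/EL reference, and `export_phantom_dicom()` emits the classic
single-frame DICOM dialect (one magnitude + three velocity series, 12-bit
phase quantization, private group-0019 tags for VENC, temporal resolution
and component labels) that `read_dicom_series()` imports, giving a
round-trip bound of VENC/2048 on velocity.

## Numerical and engineering choices

- Arrays are `[X,Y,Z,T,(component)]`; voxel indices are 0-based in physical
  formulas (position = origin + index*voxel through the direction-cosine
  rows); velocity is m/s internally, VENC carried in cm/s as acquired.
- The HDF5 container stores doubles with gzip(1)+shuffle compression and a
  fixed layout (`/magnitude`, `/velocity`, `/segmentation/*`, root
  attributes), so read(write(x)) is bit-exact. The dataset names and DICOM
  tag conventions are this package's own standard — no public convention
  exists for them.
- QC images are composed directly in pixel arrays and written with
  `png::writePNG`: no graphics device, no timestamps, no antialiasing
  state, hence byte-identical reruns. The QC verdict is a stub for human
  review (acceptance = one contiguous region covering AAo, arch and DAo,
  nothing extraneous); no automated pass/fail heuristic is claimed.
- Batch execution is sequential; per-job isolation makes results
  independent of execution order, so the contract is parallelizable even
  though the shipped runner is serial.
- Problem sizes in the test suite: unit tests run on a compact 40x24x40
  U-tube (12 frames); the end-to-end repeatability check runs the full
  default 64^3 phantoms, ten seeds, pipeline twice (~5 minutes on one
  CPU); analytic KE/EL checks use the 1 mm cylinder. Wall-clock figures
  are machine-dependent and are reported, not asserted.

## Known limitations

Temporal-only unwrapping misses voxels aliased in all frames. The
threshold segmentation fallback assumes the aorta dominates the PC-MRA;
datasets where other vessels are brighter need an external mask. The
region split is geometric, not anatomical. Flow at the vessel openings is
underestimated by partial volume. PWV assumes a measurable systolic
upslope at every plane and a single coherent wave; severe regurgitation or
very low temporal resolution will degrade the delay estimates before the
r^2 guard catches them.
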