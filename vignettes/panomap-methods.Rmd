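---
title: "panomap: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panomap: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panomap` reconstructs the epicardial surface of a rotating,
Langendorff-perfused heart from silhouettes, maps multi-camera
voltage-dye fluorescence movies onto that surface, and computes the
standard electrophysiological maps. This vignette records the models,
the coordinate conventions, the numerical choices, and the places where
the design was genuinely open — the details a maintainer or a reviewer
of a study built on this package would want.

## Coordinate conventions

The **world frame** is defined by the calibration cuboid: origin at the
cuboid center, +z along its height (the rotation axis of the stage by
default), units those of the cuboid (inches for the rabbit-scale
1 × 1 × 2 target). All geometry keeps these units.

A **camera** looks down its +z axis; `world_to_camera()` is
`p -> R p + t`. Pixel coordinates are 0-based, u right, v down, pixel
centers at integer coordinates; image arrays are `[row = v + 1,
col = u + 1]`. The camera viewing direction (`camera_normal()`) is the
world-frame optical axis, pointing *into* the scene, so a mesh face
squarely facing a camera makes an angle near 180° with it.

The **stage rotation** at angle `a` turns the object by `R_axis(-a)`;
carving therefore projects the material point `R_axis(-a) p` against the
silhouette taken at `a`. The silhouette renderer uses the identical
convention, so synthetic stacks and the carver agree by construction.
The axis is configuration (default world +z through the origin): how the
cannula axis relates to the cuboid frame is a property of the individual
rig, not something the software can infer.

## Camera model and calibration

The pinhole model has extrinsics `(R, t)` and intrinsics: focal length
`f` (pixels), aspect ratio `s` (the vertical focal length is `s f`),
principal point `(u0, v0)`, and one radial distortion coefficient `k1`
acting on normalized coordinates, `x' = x (1 + k1 r^2)`. `k1` is frozen
at 0 by default — the long C-mount lenses these rigs use show little to
no distortion — and can be estimated with
`calibrate_camera(..., estimate_k1 = TRUE)`. A single radial term was
chosen because the exact distortion parameterization used by earlier
panoramic systems is not printed anywhere we could verify; one even-order
radial term is the standard minimal model.

The cuboid grid is inset half a grid spacing from each face border and
spaced `grid_spacing`, giving 4 columns × 8 rows = 32 junctions per
1 × 2 inch face, hence the canonical 64 junctions when two faces are
visible corner-on. Junction *detection* blurs the image at the line
scale (`sigma`, default 2 px) and finds strict 2-D maxima of the
inverted intensity gated by the determinant of the Hessian: a crossing
of two dark lines is a genuine 2-D extremum, while a lone line is a
ridge with one near-zero curvature. Sub-pixel refinement is one Newton
step on the blurred intensity, whose gradient vanishes exactly at the
crossing. (A Harris corner detector was tried first and rejected: on
line crossings it fires on the four corner points *around* the junction,
biasing every detection by over a pixel.)

Junction *labeling* arranges the detections into image rows and columns
and tests each adjacent face pair as the visible pair, keeping the
hypothesis whose direct linear calibration reprojects best. A square
cuboid maps onto itself under 90° rotations, so these hypotheses can tie
exactly; the two-anchor interface (the user names the top-left and
bottom-right visible junctions, as the acquisition protocol does)
resolves the ambiguity and also handles partially visible grids. The
automatic path assumes a roughly upright camera (rows separable by v);
anchors cover the rest.

*Calibration* minimizes the stacked 2-D reprojection residuals over
`(rodrigues(R), t, f, s, u0, v0[, k1])` with Levenberg–Marquardt
(`minpack.lm`), converging at relative residual change `1e-10` or 200
iterations, seeded by a normalized 11-parameter DLT followed by RQ
decomposition (skew discarded). The 3-D junction coordinates are held
fixed — no bundle adjustment — because the machined target's geometry
is known far better than any single-view estimate of it would be.
`reprojection_rmse()` is the root mean of squared per-point Euclidean
distances, so a uniform 1 px shift gives exactly 1 px.

## Silhouettes and visual-hull carving

Segmentation is Otsu thresholding (heart darker than backdrop; a
polarity flag flips this), polygon add/remove edits applied in order,
hole filling, and largest-component selection. Holes are filled because
specular highlights on the epicardium otherwise punch holes through the
silhouette that would carve spurious tunnels through the hull; the
silhouette of a heart is simply connected.

Carving intersects back-projected silhouette cones on an octree. A
voxel's eight corners are projected into every view (nearest-pixel
lookup — the corners are projected as points, not footprints;
projections off the image count as outside): all corners inside every
silhouette → inside; otherwise the voxel is subdivided until
`max_depth`, where mixed voxels get occupancy 0.5 (inside 1, outside 0).
Voxels whose corners are all outside are *not* discarded outright —
corner sampling can miss a thin intersection — but only when their
projected bounding box misses some silhouette entirely (an O(1) test on
a summed-area table of each mask). This conservative pruning is what
makes the octree provably identical, cell for cell, to brute-force
classification of the full finest grid for convex silhouettes, a
property the test suite checks exhaustively at depth 5.

Default bounds are a cube 1.2× the largest back-projected silhouette
extent, centered on the rotation axis ("slightly larger than the
heart"); default `max_depth` is 7 (128³ finest cells). Boundary voxels
carry 0.5 so the isosurface passes through them; assigning them 1 would
bias the hull outward by a full voxel.

## Meshing and smoothing

`extract_surface()` is marching tetrahedra on the Freudenthal 6-tet
cube subdivision of the cell-center lattice. This variant of the
marching-cubes family was chosen because its per-tetrahedron case table
is tiny and unambiguous and the Freudenthal split is
translation-consistent across cube faces, so the mesh is watertight and
consistently wound (outward, positive enclosed volume) by construction
rather than by table audit. Two numerical details:

* samples exactly equal to the iso level (the 0.5 boundary cells) are
  treated as inside and internally offset to the midpoint between iso
  and the inside value, so edge interpolation is never degenerate and
  no zero-area triangles are emitted;
* for occupancy input the three-valued field is first averaged over a
  3³ box (`antialias = TRUE`). The raw {0, 0.5, 1} indicator quantizes
  the surface to voxel faces and biases the enclosed volume outward by
  a substantial fraction of a voxel; the box-filtered indicator's
  0.5-level tracks the hull boundary with most of that staircase bias
  removed. Both behaviors can be disabled or bypassed by passing a raw
  scalar field.

Smoothing is Taubin's λ|μ scheme (uniform weights; defaults
`iterations = 50, lam = 0.5, mu = -0.53`): alternating positive and
negative Laplacian steps that damp the voxel staircase while roughly
preserving volume, unlike plain Laplacian smoothing which shrinks
towards a point. Connectivity is never modified.

## Signal conditioning

The conditioning order is normalize → 3 × 3 box binning → 100th-order
FIR low-pass (0–100 Hz) → first-order drift removal. Normalization is
per-pixel min–max over time (the standard choice in optical mapping,
where dye loading and illumination vary strongly across the image;
whether to normalize per-pixel or globally is not fixed by any printed
source, so per-pixel was chosen and a `normalize_first = FALSE` switch
reorders filtering before normalization for users who prefer it).
Binning averages only foreground pixels, so background zeros never
bleed into the tissue signal. The band pass with a 0 Hz lower edge is
implemented as the degenerate case it is — a low-pass — designed as a
Hamming-windowed sinc (`signal::fir1`), re-normalized to exactly unit
DC gain, applied by FFT convolution on edge-replicated traces with the
`order/2`-sample group delay removed, so wave timing is not shifted.
The sampling rate is required configuration (default 1000 Hz, typical
of the CMOS acquisition hardware these rigs use); it is not printed
anywhere authoritative.

The blending **weight mask** is `w = 0.5 + 0.5 (d - d_min) /
(d_max - d_min)` with `d` the Euclidean distance to the nearest
background pixel (the image border counts as background): exactly 0.5
on the outermost foreground pixels, exactly 1 at the deepest, linear in
between. The endpoint values are fixed by the protocol; the linear ramp
between them is this package's choice (any monotone profile with those
endpoints would satisfy the stated rule).

## Projection and blending

For each camera, each mesh face gets the angle `theta` between its
outward normal and the camera viewing direction: `theta < 90°` excluded,
`90° ≤ theta ≤ 115°` edge (closed interval, stabilized by a 1e-7°
tolerance), `theta > 115°` assigned. Visibility is decided by normals
only — no z-buffer — exactly as the texture-mapping protocol states;
this is correct for convex hearts and slightly optimistic in deep
concavities. Face traces are then:

* assigned by exactly one camera → that camera's nearest-pixel trace;
* assigned by several (overlap) → `sum(w_i s_i) / sum(w_i)` with `w_i`
  the weight-mask value at the projected pixel;
* edge only → the same weighted average over every camera classifying
  the face edge or assigned (mask weight only; whether an extra
  angle-dependent taper should multiply the mask weight is not
  specified anywhere, so none is applied);
* a camera whose projected pixel is out of frame, background, or has
  zero weight contributes nothing; faces with no contributor are
  excluded and carry missing signal.

Every blend is a convex combination, so projected traces never leave
the range of their camera traces.

## Electrophysiological maps

* **Activation** = time of maximum temporal derivative (the
  optical-mapping dV/dt-max convention; a 50%-crossing alternative sits
  behind `method = "midpoint"`), parabolic sub-sample refinement, ties
  broken to the center of the maximal run; the refinement is skipped on
  delta-like derivatives (step upstrokes) where a quadratic fit is
  meaningless.
* **APD** at level `L` = first time after the AP peak the trace falls
  below `peak - L (peak - baseline)`, linearly interpolated, minus the
  activation time (activation-to-recovery convention; APD is invariant
  to affine rescaling of the trace by construction).
* **Dominant frequency** = Welch periodogram peak (Hann windows, 50%
  overlap) within a 0.5–50 Hz search band. The segment-averaged
  periodogram is implemented directly on `stats::fft`; the test suite
  cross-checks its peak against `stats::spec.pgram`.
* **Phase** = argument of the FFT-computed analytic signal of each
  mean-subtracted trace, wrapped to `(-pi, pi]`.
* **Phase singularities**: the four wrapped phase differences around
  every 2 × 2 pixel loop are summed; ±2π (tolerance 1e-6) marks a
  singularity of that chirality at the loop center. Detection runs on
  2-D rasters (camera images or unwrapped maps); per-face mesh loops
  are an extension point, not the default. None of these algorithms is
  pinned down in print for the original toolchain; Hilbert phase and
  loop topological charge are the field's standard choices and are
  documented here as such.

## Unwrapping

The closed mesh is parameterized by centroid direction about the
long/rotation axis (translated to the mesh centroid): latitude from the
angle to the equatorial plane, longitude from the azimuth. This is a
deliberate substitution — how the original tools flatten a non-spherical
heart is not described — and it is single-valued only for star-shaped
surfaces about the centroid, which carved ventricular hulls are in
practice. Mercator (`x = lon`, `y = ln tan(45° + lat/2)`, clamped to
±85° latitude with the polar caps reported missing) and the equal-area
Hammer projection are rasterized by nearest-face lookup on the sphere —
no interpolation, so isochronal discontinuities stay sharp and every
raster value is an actual face value.

## The synthetic study and what it does (not) show

All tests run on generated data, because no public panoramic data set
exists. The generators emulate: a ray-traced gridded cuboid with exact
junction ground truth; rotation silhouettes of analytic solids
(exact ray–solid intersections at pixel centers); and per-camera movies
in which every pixel ray hitting the solid carries a piecewise-linear
action potential (closed-form APD at any level) timed by a plane-wave,
focal, or spiral pattern. Four optical cameras sit at 45°, 135°, 225°
and 315° azimuths — corner-on to the cuboid so each sees 64 junctions —
at 10 units distance, f = 400 px, 100 × 100 px sensors; the geometry
camera uses a 160 × 160 sensor. A plane wave at 0.02 units/ms over a
0.8-unit-radius sphere fills a 250 ms recording at 1000 Hz.

The defaults emulate the rabbit-scale study geometry; the defaults are
deterministic given the seed, and noise is additive Gaussian only. The
fixtures do not emulate: motion, photobleaching beyond a linear trend,
dye heterogeneity, optical blur, camera noise statistics, or concave
anatomy (atrioventricular grooves). Passing tests therefore demonstrate
the correctness of the geometry and signal chain, not robustness to
every artifact of live-heart data.

Problem sizes used by the test suite, chosen to exercise every code
path at meaningful resolution: octree–brute-force equivalence at depth
≤ 5 on three views; sphere carving at depth 7 from 72 views of a
160 × 160 geometry camera; the end-to-end study at depth 5 with four
100 × 100 cameras and 250 ms movies; calibration noise runs over 20
seeds; APD Monte-Carlo over 100 seeds.

## Known limitations

* Normal-only visibility (no occlusion test) misassigns faces inside
  deep concavities; an optional z-buffer is a planned extension.
* The automatic (anchor-free) labeler requires the full two-face grid
  and an upright camera, and for square cuboids is only defined up to
  the target's 4-fold symmetry — use anchors there.
* 32-bit-sample TIFFs are interpreted as floating point (as written by
  this package); external uint32 TIFFs are not supported.
* The spherical parameterization assumes a star-shaped surface;
  strongly non-convex meshes would need a true surface flattening,
  which is out of scope.
* File-input pipelines are assembled from the module functions (or the
  CLI subcommands); the one-call `run_pipeline()` orchestrates the
  simulated study.
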