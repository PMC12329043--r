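---
title: "Telecentric stereo 3D measurement: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telecentric stereo 3D measurement: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telestereo)
```

## The measurement problem

Small biological specimens — the motivating application is pinned
Lepidoptera — need non-invasive 3D morphometry at micrometre accuracy over a
measurement volume of roughly 11 mm × 11 mm × 6 mm. A practical instrument
for this is a *telecentric stereo* rig: two cameras behind telecentric
lenses view the specimen at a fixed stereo angle while a projector paints it
with a sequence of varying illumination patterns. Each surface point then
carries a distinctive intensity *time series*; matching those series between
the two cameras yields dense correspondences, and triangulation yields a
metric point cloud. 2D measurements of curved structures (an antenna, say)
underestimate true lengths through foreshortening — a 3D polyline over the
reconstruction does not.

This package implements the full chain at desk scale: the affine camera
model, a synthetic replacement for the physical rig with exact ground truth,
temporal-correlation matching, the extrinsic calibration with its
telecentric-specific failure mode and correction, and the validation
geometry (plane/sphere fits, residual statistics, quality filters).

## The telecentric (affine) camera

A telecentric lens performs a parallel projection: chief rays are parallel
to the optical axis, so magnification does not depend on depth. With
magnification $M$ and pixel pitch $pp$, the intrinsic matrix is diagonal,

$$K = \begin{bmatrix} M_x/pp & 0 & 0 \\ 0 & M_y/pp & 0 \\ 0 & 0 & 1
\end{bmatrix},$$

with no principal point and no shear. Projection of a world point $X$ is
$u = (M_x/pp)\,(RX+t)_1$, $v = (M_y/pp)\,(RX+t)_2$; the third camera
coordinate never enters. Consequences used throughout:

* pixel coordinates are **centred** (the affine model fixes no principal
  point, so the convention must be explicit: $(0,0)$ is the image centre,
  $u$ rightward, $v$ downward);
* all viewing rays of one camera share a single direction $R^\top e_3$
  (their meeting point lies at infinity), so back-projection returns
  parallel rays and triangulation intersects two ray bundles;
* depth precision comes entirely from the stereo angle: the depth error of
  a triangulated point scales as $1/\sin\theta$ — verified in the test
  suite as the $\sin 40^\circ/\sin 20^\circ$ ratio law;
* the reconstruction scale comes from $K$, not from the baseline length
  (parallel rays translate, they do not diverge), which is why the baseline
  magnitude is unrecoverable and why a printed intrinsic convention error
  shows up as a *global* scale factor, fixable with a calibration plate
  (`estimate_scale()`).

Internal units are millimetres everywhere; intrinsics printed in px/m on
data sheets convert to px/mm on input. Anisotropic magnification
($M_x \neq M_y$) is supported, as real lens/sensor combinations are never
perfectly isotropic. The magnification convention deserves one note: for a
lens of nominal magnification in the 0.69–0.88× range with $pp =
2.74\,\mu m$, $K_{11} = M/pp \approx 252$ px/mm corresponds to $M \approx
0.69$ and an object-space pixel of $4\,\mu m$; data sheets sometimes quote
the reciprocal ("effective magnification 1.46"). The package stores $M$
such that $K = M/pp$ and leaves reconciling vendor conventions to the user.

## The synthetic rig

`default_rig()` builds two cameras whose axes intersect at the origin at a
stereo angle of 38.5° (the reference instrument's geometry), and a parallel
projector along $-z$. Defaults emulate the reference instrument with a
*binned* sensor: 256 × 256 px with pitch scaled by 2848/256 so the
11.3 mm field of view is preserved while a full pipeline run takes seconds.
All geometry is scale-free; passing `image_size = c(2848, 2848)` and
`pixel_pitch = 2.74e-3` reproduces the physical sensor.

Camera 2 is mounted *rolled by 180° about its own optical axis* by default
(`roll_camera2 = TRUE`). Physical dual-camera rigs are commonly assembled
this way, and the printed calibration of the reference instrument has
exactly this structure (its correct rotation matrix is $R_z(180°)R_y(\sim
50°)$ to three digits). The mounting matters for the identity rule of
thumb discussed below.

Patterns are band-limited pseudo-random noise: white noise low-pass
filtered at a cutoff (default 0.1 cycles/px) and rescaled to $[0,1]$. The
projector is modelled as a *parallel* projector — the physical device is
stopped down for depth of projection, and the parallel model keeps the
pattern value at a surface point analytic, hence exact correspondence
ground truth. Scenes are single analytic surfaces (plane with optional
Gaussian roughness, sphere, dot-grid plate with bright circles of albedo
0.9 on a 0.05 background at known spacing); the renderer intersects each
pixel ray with the surface, samples the pattern bilinearly, applies albedo,
and adds clipped Gaussian intensity noise. What the simulator deliberately
does **not** model: cast shadows, inter-reflections, speckle, defocus,
vignetting, colour. Passing tests on this data therefore demonstrates the
*geometry and algorithms*, not robustness to photometric artefacts of real
scattering specimens.

## Temporal-correlation matching

The match score between a pixel of camera 1 and a pixel of camera 2 is the
zero-mean normalized cross-correlation of their intensity time series over
the pattern sequence (100 frames by default). The search is exhaustive at a
coarse stride for calibration, then restricted to a band of ±2 px around
the affine epipolar line for dense reconstruction. Integer peaks are
refined by fitting a paraboloid to the 3 × 3 correlation neighbourhood
(clamped to ±0.5 px); peaks on the search-region border are dropped, and a
peak that is already exactly 1 is not refined. Ties at the integer argmax
break deterministically toward the smallest linear pixel index.

Two practical guards matter on realistic data:

* **Modulation floor** (`min_modulation`, default 0.02 intensity units):
  an unlit background pixel carries pure sensor noise, and the *maximum*
  correlation of pure noise over $N$ candidates concentrates around
  $\sqrt{2\ln N / n_{frames}}$ — about 0.4–0.5 for a full-image search at
  100 frames, i.e. above the 0.3 threshold used for difficult scattering
  surfaces. Masking pixels with negligible temporal modulation removes
  these spurious extreme-value matches, as is standard in structured
  illumination.
* **Occlusion outliers**: a surface region visible to camera 1 only still
  produces a best match somewhere; correlation thresholds alone cannot
  remove all of these. Calibration therefore trims epipolar-residual
  outliers (3× median, two rounds) before the final fit, and validation
  statistics follow the standard protocol of thresholding at 0.9, while
  the dense reconstruction itself may keep everything above 0.3.

Correlation thresholds: 0.9 retains only high-confidence points and is used
for precision statistics on cooperative surfaces (reference plane,
metrology sphere); 0.3 is the working threshold for difficult, scattering
objects. An optional left-right consistency check exists but is off by
default, since the workflow relies on correlation thresholds.

## Extrinsic calibration and the telecentric model mismatch

The relative orientation is estimated from correspondences of a measured
reference object (a sphere). The affine fundamental matrix — zero
upper-left 2 × 2 block — is estimated by the linear Gold-Standard method
with Hartley normalization. Then, deliberately, the *pinhole-style* route
is followed: $E = K_2^\top F K_1$, projection to the essential manifold,
and the standard two-rotation decomposition, yielding candidates
$\{R_a, R_b\} \times \{+t, -t\}$. This reproduces what general-purpose
libraries produce when applied naively to telecentric data, including its
failure: the pinhole model explains affine disparities as a small rotation
plus a lateral translation, so the discrete candidates are a near-identity
"re-projection" rotation and its 180° twin — not the true second
perspective.

The deeper reason is a genuine ambiguity of two-view parallel projection
(the bas-relief ambiguity): the affine epipolar geometry constrains only
the *directions* of $(r_{13}, r_{23})$ and $(r_{31}, r_{32})$ of the
relative rotation. Their common magnitude $\rho$ (the turn angle) and the
sign of $r_{33}$ are invisible to any two telecentric views, and the
rotation is additionally only determined up to the mirror (Necker)
equivalence $R \sim D_z R D_z$, $D_z = \mathrm{diag}(1,1,-1)$, whose two
members reconstruct congruent (possibly reflected) geometry. All rotation
comparisons in the package respect this equivalence
(`rotation_distance(mod_mirror = TRUE)`).

What breaks the ambiguity is the *reference shape*:
`select_by_reference()` triangulates the calibration correspondences under
each candidate, fits the reference, and ranks candidates by residual
standard deviation. When the candidate set carries the estimated $F$ (the
usual case), the selection additionally refines $\rho$ along the four sign
branches of the affine-consistent rotation family — a 1-D optimization per
branch. A sphere pins $\rho$ sharply: a wrong turn angle turns the
reconstructed cap into an ellipsoidal surface whose sphere-fit residual is
orders of magnitude above the noise floor. Noise-free recovery is
$\sim 10^{-6}$ degrees; the depth-reversed branch is rejected by factors
of $10^5$ or more. A *plane* reference, in contrast, validates
reconstruction quality but cannot reject wrong candidates — an affinely
distorted plane is still a plane — and a plane scene cannot even constrain
$F$ (its two images are related by a single 2D affine map). This is why
the calibration object is a sphere.

**The identity rule of thumb.** For quick work without a reference fit,
the rule "the candidate rotation deviating more from the identity is
(usually) correct" is provided (`select_by_identity_rule()`, Frobenius
distance, with an ambiguity error when the margin is below $10^{-6}$). Its
validity is mount-dependent: for a rolled mount the true relative rotation
is a ~180° rotation — the largest possible deviation from identity — so
the rule identifies it reliably (≥ 95% over randomized rigs with up to 2°
mount perturbation in the test ensemble, baselines drawn as the
decomposition produces them); for an unrolled symmetric mount the true
rotation is *small* and the rule would prefer the wrong twin. The rule is
reported for audit in `calibrate_stereo()`; the reference selection is
authoritative.

**Translation sign.** The baseline sign is immaterial: with parallel rays,
flipping $t$ translates every camera-2 ray by the same constant vector, so
the two reconstructions differ by a rigid offset and have identical
residual statistics. (In pinhole processing the same sign flip manifests
as coordinate sign changes; the telecentric analogue is the pure offset.)
Reconstructions are expressed in camera-1 coordinates.

**Metric scale.** The affine baseline magnitude is unrecoverable, and
intrinsic-convention errors scale reconstructions globally. A dot-grid
plate of known spacing fixes this: `estimate_scale()` projects the feature
cloud onto its best-fit plane, clusters features by single linkage with an
adaptive cut (5× the median nearest-neighbour distance; fragments below
three points rejoin their feature in one reassignment pass), and compares
the modal centre spacing — the median over all adjacent centre pairs,
which avoids the downward bias of per-point minimum statistics — with the
true spacing.

## Validation geometry

* `fit_plane()`: total-least-squares plane via the eigendecomposition of
  the centred covariance; signed orthogonal residuals.
* `fit_sphere()`: algebraic linear initialization refined by damped
  Gauss–Newton on geometric distances; optionally with the radius fixed,
  the regime for reference spheres of trusted nominal radius (a free
  radius is the default in disambiguation because a printed nominal
  radius may be slightly off). Coplanar input with a free radius is a
  degeneracy error.
* "Standard deviation" is the *population* std of signed residuals about
  the fitted shape; at the $n \sim 10^5$ scale of real clouds the
  sample/population distinction is negligible, but the convention is
  fixed.
* `filter_by_score()`, `central_patch()` (innermost fraction of points by
  radial distance from the viewing axis through the centroid; default
  fraction 0.485 — note the source material that motivates this default
  prints both "18.5%" and "48.5%" for the same analysis; the fraction is
  therefore an explicit parameter), `crop_box()` (manual platform
  removal), `residual_stats()` (population std + fixed-width histogram,
  default bin width std/10), `polyline_length()`.

Reconstruction error grows with the local surface slope against the
viewing direction — the correlation peak flattens as the pattern
foreshortens — so central patches show tighter residuals; the property
tests encode this with a slope-dependent error law ($\propto 1/\cos^2$),
which dominates the purely geometric projection factor of the residual.

## Numerical choices

* Hartley-style centring/scaling before the $F$ estimate (intrinsic
  entries are $\sim 10^2$–$10^5$; raw conditioning is poor); degeneracy is
  detected from the singular-value spectrum of the normalized coordinate
  matrix.
* The essential projection tolerates the inherent rank-2 structure of
  affine $E$; a numerically rank-3 $E$ is an input error.
* The bas-relief refinement uses `optimize()` on $\rho \in [10^{-3},
  1-10^{-9}]$ with tolerance $10^{-10}$, per sign branch; each evaluation
  is a vectorized triangulation plus one shape fit.
* Sphere Gauss–Newton applies step halving when a step would increase the
  residual sum; the paraboloid subpixel fit solves the stationary point of
  the least-squares quadric over the 3 × 3 neighbourhood and clamps to
  ±0.5 px.
* Ties (integer argmax, central-patch ranking) break deterministically by
  index; all generators accept explicit seeds and restore the caller's
  RNG state, so identical seeds give bit-identical stacks, matches and
  PLY files.

## Problem sizes

The shipped experiments run at the desk scale the package defaults to:
256 × 256 px stacks of 100 frames for the end-to-end sphere experiment
(matching at stride 4 for calibration and stride 2 within a ±2 px epipolar
band for reconstruction, a few seconds each), 60-rig ensembles for the
disambiguation study, $10^4$–$10^5$ points for the statistical
consistency checks. These sizes were chosen so the complete suite
reproduces the method's behaviour in minutes on one CPU while leaving all
geometric parameters at instrument values.

## Known limitations

* No lens-distortion model: telecentric optics are treated as ideal,
  mirroring the design decision of the instruments this emulates; residual
  optical distortion in real data appears as systematic depth error at the
  field edges.
* Single-view reconstructions only; multi-view registration to closed
  360° models is out of scope.
* The identity rule is advisory and mount-dependent (see above).
* The synthetic projector is parallel and shadow-free; real projector
  defocus, speckle and inter-reflections degrade correlation in ways the
  simulator does not emulate.
* Matching assumes a static scene across the pattern sequence.
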