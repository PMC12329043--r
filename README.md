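# telestereo

Telecentric stereo 3D measurement with structured illumination, in R.

Small, delicate specimens — the motivating case is pinned Lepidoptera
(moths) — need micrometre-accurate, non-invasive 3D morphometry. A pair of
cameras behind telecentric lenses at a fixed stereo angle, plus a projector
cycling through varying illumination patterns, delivers exactly that: every
surface point carries a distinctive intensity time series, temporal
normalized cross-correlation matches those series between the cameras, and
triangulating the matched parallel rays yields a metric point cloud. The
payoff over 2D imaging is concrete: a curved antenna measured in a 2D
projection is foreshortened, while its 3D polyline length is not.

The scientific core of the package is the telecentric-specific extrinsic
calibration. A telecentric lens is an *affine* camera — its intrinsic
matrix is diagonal,

    K = | M/pp   0   0 |
        |  0   M/pp  0 |        (M = magnification, pp = pixel pitch)
        |  0     0   1 |

and its viewing rays are parallel. Feeding such data through the standard
pinhole pipeline (fundamental matrix → essential matrix → two rotations ±
translation) produces a candidate set in which the wrong, near-identity
rotation looks plausible: two parallel-projection views genuinely do not
determine the turn-angle magnitude of the relative rotation (the bas-relief
ambiguity). The package reproduces that failure faithfully and then corrects
it the way a metrologist does: by measuring a reference sphere, triangulating
under each candidate, and selecting — and refining along the affine-consistent
rotation family — the extrinsics whose reconstruction actually fits the
sphere. A deviation-from-identity rule of thumb is included for audit, and a
dot-grid plate of known spacing establishes the metric scale.

Everything is testable at desk scale without hardware: a synthetic rig
renders pattern stacks onto analytic scenes (plane, sphere, dot grid) with
exact ground truth. Point clouds and correspondences are tibbles; fits have
`tidy()`, `glance()` and `autoplot()` methods; clouds interchange with
external viewers as ASCII PLY (binary little-endian is read too).

## Worked example: the synthetic sphere experiment

Simulate a 2.5 mm resin sphere under the default rig (38.5° stereo angle,
100 patterns, 256×256 px preserving the instrument's 11.3 mm field of view,
intensity noise 0.02), calibrate on it, reconstruct densely, and validate:

```r
library(telestereo)

rig   <- default_rig()                                  # 38.5 deg, rolled mount
scene <- scene_sphere(center = c(0.2, -0.1, 0.5), radius = 2.5)
sim   <- simulate_measurement(scene, rig, n_frames = 100,
                              noise_sigma = 0.02, seed = 7)

cal <- calibrate_stereo(sim$stack1, sim$stack2, rig$cam1, rig$cam2,
                        reference = "sphere")
cal
#> <stereo calibration>
#> <extrinsic candidate set {R_a, R_b} x {+t, -t}>
#>   ||R_a - I||_F = 2.8284   ||R_b - I||_F = 2.8284
#>   t_unit =  1.00000 -0.00019  0.00000
#>   identity rule: ambiguous (... margin < 1e-6; use select_by_reference())
#>   reference selection: std 0.005023 mm
#>              [,1]         [,2]         [,3]
#> [1,] -0.782829000  5.52944e-05  0.622237000
#> [2,] -0.000165789 -1.00000e+00 -0.000119714
#> [3,]  0.622237000 -1.96876e-04  0.782829000
```

The decomposition's discrete candidates are both 180°-type rotations
(equidistant from the identity — the rule of thumb abstains), while the
reference fit pins the relative rotation: the selected matrix is
Rz(180°)·Ry(38.5°) to ~0.02°, i.e. the true rolled-mount geometry
(cos 38.5° = 0.7828, sin 38.5° = 0.6222 appear directly in the matrix).

```r
cloud <- reconstruct_cloud(sim$stack1, sim$stack2, rig$cam1, rig$cam2, cal,
                           stride = 2, min_score = 0.3)
cloud
#> <point cloud: 2373 points, score 0.301-0.985>

v <- validate_cloud(cloud, "sphere", min_score = 0.9)
v$fit
#> <sphere fit: n = 2184, residual std = 0.005005 mm (5 um)>
#>   center =  0.0252711 -0.100189 -2.14419   radius = 2.499 mm
glance(v$fit)
#> # A tibble: 1 x 6
#>   model      n  std_mm std_um rmax_mm radius_mm
#>   sphere  2184 0.00500   5.00  0.0227      2.50
```

The dense match keeps everything above the scattering-surface threshold 0.3;
precision statistics use the standard 0.9 outlier threshold. The free-radius
sphere fit recovers 2.499 mm (0.04% error) with a 5 µm residual standard
deviation, consistent with the injected noise propagated through matching
and triangulation. The reconstruction lives in camera-1 coordinates (hence
the centre offset); `autoplot(v$fit)` draws the residual histogram and
`write_ply(cloud, "sphere.ply")` exports for external viewers.

A command-line pipeline wrapping these functions ships at
`inst/cli/telestereo.R`:

```sh
Rscript inst/cli/telestereo.R simulate --scene sphere --radius 2.5 \
        --frames 100 --angle 38.5 --seed 7 --out sim
Rscript inst/cli/telestereo.R calibrate --in sim --reference sphere
Rscript inst/cli/telestereo.R reconstruct --in sim --min-score 0.3
Rscript inst/cli/telestereo.R validate --cloud cloud.ply --model sphere
```

## Further reading

The methods vignette (`vignettes/telecentric-stereo.Rmd`) documents the
camera model and its conventions, the bas-relief ambiguity of two-view
parallel projection and why a reference *sphere* (not a plane) resolves
it, the matcher's modulation floor and outlier handling, the scale
estimation, the numerical choices, and the simulator's limitations.
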