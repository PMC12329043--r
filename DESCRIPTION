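Package: telestereo
Title: Telecentric Stereo 3D Measurement with Structured Illumination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a telecentric (affine) stereo
    photogrammetry pipeline for micrometre-accurate 3D morphometry of small
    specimens such as Lepidoptera. Provides a telecentric camera model with
    projection, ray back-projection and two-ray triangulation; a synthetic
    structured-illumination rig (band-limited noise patterns rendered onto
    analytic plane, sphere and dot-grid scenes with full ground truth);
    temporal normalized-cross-correlation correspondence search with subpixel
    refinement; affine fundamental-matrix estimation, essential-matrix
    candidate enumeration and disambiguation of the telecentric model mismatch
    against a reference shape; metric scaling from a calibration plate; and
    validation geometry (total-least-squares plane fits, free- and
    fixed-radius sphere fits, correlation filtering, central-patch selection,
    polyline lengths). Point clouds and correspondences are tibbles; fitted
    objects support tidy(), glance() and autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
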