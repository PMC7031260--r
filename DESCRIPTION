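Package: helixflow
Title: Pressure-Based Extraction and Quantification of Helical Flow in 4D Flow MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of helical and vortical blood-flow patterns
    in time-resolved three-directional phase-contrast MRI (4D flow MRI)
    velocity fields. Computes a time-resolved relative pressure map from the
    Navier-Stokes momentum balance by iterative relaxation, applies binomial
    smoothing, quantile clamping and mean centring, and segments helix/vortex
    regions as connected components of negative relative pressure. Derives
    temporal helical existence, maximum and accumulated helical volumes,
    accumulated helical volume length along the vessel centerline, and
    body-surface-area indexed volumes. Integrates time-resolved pathlines
    (fourth-order Runge-Kutta with trilinear interpolation) and classifies
    their rotation direction (handedness) by cross-sectional projection about
    the centerline. Includes conventional measuring-plane flow quantification,
    optional phase-unwrap / eddy-current / noise preprocessing, analytic
    pulsatile tube-and-vortex phantoms with closed-form ground truth, and
    paired agreement statistics (Wilcoxon signed-rank, Bland-Altman, ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    matrixStats,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
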