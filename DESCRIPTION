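Package: wingsym
Title: Anterior-Posterior Symmetry Morphometrics for Drosophila Wings and Wing Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics and image geometry for
    quantifying anterior-posterior (AP) asymmetry in the Drosophila wing.
    Provides pairwise Procrustes superimposition with disparity, construction
    of anteriorized/posteriorized (symmetrized) wings about the AP axis defined
    by vein landmark pairs, symmetry scores, convex-hull ellipse fitting and
    eccentricity of wing-disc expression patterns, intervein region-area
    quantification from vein annotations, a gated two-sample testing procedure
    (Shapiro-Wilk, Levene, t-test or Mann-Whitney U), Monte-Carlo power for the
    Mann-Whitney U test, and synthetic-data generators (wing-landmark cohorts
    with controllable asymmetry, two-channel wing-disc phantoms with known
    eccentricity and region fractions) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
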