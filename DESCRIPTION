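Package: virtucrania
Title: Virtual Reconstruction and Shape Analysis of Fragmentary Crania
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided virtual reconstruction of disarticulated cranial
    fragments and downstream geometric-morphometric analysis. Implements ordinary
    and generalized Procrustes analysis, 3D thin-plate-spline warping, reference
    ranking and fragment re-assembly (the DTA protocol), missing-landmark
    estimation, shape-space PCA with out-of-sample projection, surface
    semilandmark projection and sliding, endocast warping for cranial-capacity
    estimation, contour-polyline slicing of surface meshes, occipital shape
    comparison, and discrete-trait neighbour-joining and exhaustive maximum
    parsimony with strict consensus. A seeded synthetic-specimen generator
    provides cranium-like meshes, landmark configurations, endocasts and
    character matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
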