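Package: harmonichex
Title: Harmonic-Field Hexahedral Meshing and Orthotropic Finite Elements
    for Scleral Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic all-hexahedral meshing of open two-surface shell
    geometries, such as the posterior sclera of the human eye, driven by a
    harmonic scalar field on the bounding triangle surfaces.  A cotangent
    Laplacian with Dirichlet constraints on the two boundary rings (optic
    nerve head canal and equator) yields the field; gradient streamlines and
    even-valued isocontours form structured quadrilateral grids on the outer
    and inner surfaces which are stacked into 8- or 20-node hexahedral
    elements.  The same field supplies per-element orthotropic material
    frames (circumferential, meridional, thickness).  A small linear
    finite-element solver for orthotropic elasticity under inner-surface
    pressure, with dihedral-angle mesh-quality statistics, region-wise
    result maxima and an isotropic-versus-anisotropic comparison study,
    completes the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
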