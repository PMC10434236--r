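Package: wmphantom
Title: Dense White-Matter Fibre Substrates for Monte Carlo Diffusion Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic white-matter numerical phantoms for
    Monte Carlo diffusion-MRI simulation. Fibre bundles are initialised by
    two-dimensional disk packing with gamma-distributed radii and a target
    angular dispersion, disentangled by a capsule-based joint optimization
    with an analytic overlap cost and its gradients, densified by a
    voxel-based fibre radial growth with per-fibre radius caps, and given
    myelin compartments by morphological erosion toward a target g-ratio.
    Watertight triangle meshes of the inner and outer fibre surfaces are
    extracted for simulator use, and the package measures axon, myelin and
    fibre volume fractions, aggregate g-ratio, equivalent-radius profiles,
    radii distributions and orientation dispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
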