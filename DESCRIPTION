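Package: specular
Title: Model-Based Analysis of Specular Neutron and X-Ray Reflectometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward calculation and refinement of specular neutron and X-ray
    reflectivity R(Q) from stratified interfacial models.  Models are
    hierarchical (laterally mixed patches of layer stacks) and layer entries
    may be symbolic expressions in named parameters, enabling compact
    definitions of nanoparticle layers, polymer brushes and solvent-penetrated
    lipid bilayers.  Reflectivity is computed with the Abelès transfer-matrix
    method with Névot-Croce interfacial roughness, Gaussian resolution
    smearing, incoherent patch averaging, and scale/background corrections.
    Refinement of one or several co-refined curves (contrast variation,
    polarised pairs) uses differential evolution with inequality constraints;
    parameter uncertainty is estimated by Hessian curvature, bootstrap
    resampling, or affine-invariant ensemble Markov chain Monte Carlo with
    autocorrelation-based chain management.  A synthetic-data generator with a
    realistic counting-noise model supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
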