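Package: trabfab
Title: Trabecular Bone Morphometry, MIL Fabric Tensors, and
    Fabric-Based Elastic Homogenization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of binarized micro-computed
    tomography volumes of cancellous bone.  Computes standard morphometric
    indices (bone volume fraction, surface density by isosurface
    triangulation, local trabecular thickness and separation, connectivity
    density via the Euler characteristic, ellipsoid factor), measures
    structural anisotropy with the mean-intercept-length (MIL) method and
    the associated second-rank fabric tensor, and maps fabric plus bone
    volume fraction to a homogenized orthotropic elasticity tensor using
    Cowin's fabric-elasticity relations with empirically fitted
    volume-fraction functions.  Includes seeded synthetic-volume
    generators (analytic phantoms and anisotropic Gaussian-random-field
    trabecular emulators), cohort-level power-law regression of moduli on
    bone volume fraction, and a voxel-size sensitivity study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
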