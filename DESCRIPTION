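Package: ecgisim
Title: Simulation and Inverse Reconstruction of Ventricular Excitation for
    Electrocardiographic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in silico pipeline for studying electrocardiographic imaging
    (ECGi). Builds idealized truncated-ellipsoid bi-ventricle voxel geometries
    with rule-based fiber orientation, simulates human ventricular excitation
    with the ten Tusscher-Panfilov (2006) cell model coupled through an
    anisotropic monodomain reaction-diffusion solver, computes body-surface
    potentials with a boundary-element forward solver on a synthetic torso,
    reconstructs epicardial potentials by zero-, first- and second-order
    Tikhonov regularization with GSVD filtering and L-curve parameter
    selection, and quantifies how heart-geometry mismatch and pacing rate
    degrade reconstruction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
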