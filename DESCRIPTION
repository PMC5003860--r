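Package: wfomtools
Title: Wide-Field Optical Mapping Spectroscopy and Haemodynamic
    Cross-Talk Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts multi-wavelength diffuse-reflectance movies of the
    exposed cortex into oxy-, deoxy- and total-haemoglobin concentration
    maps via the modified Beer-Lambert law, estimates the
    wavelength-dependent photon pathlengths and spatial sensitivity that
    the conversion requires with a Monte Carlo model of light transport
    in scattering tissue, corrects wide-field fluorescence (e.g. GCaMP)
    recordings for multiplicative haemodynamic cross-talk by
    single-wavelength, excitation-emission and PCA-based methods, and
    unmixes haemodynamic movies into vascular-compartment contribution
    maps by seeded non-negative least squares. A synthetic-phantom
    generator provides forward-modelled reflectance and fluorescence
    movies with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
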