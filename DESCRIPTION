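Package: carotidrisk
Title: Carotid Hemodynamics, Plaque Stress and Cerebrovascular Event Risk
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for cerebrovascular event risk modelling in
    carotid artery disease. Generates synthetic planar carotid bifurcation
    geometries, plaque-bearing cross-sections and imbalanced patient cohorts;
    builds pulsatile inflow boundary conditions from Doppler ultrasound
    landmarks (peak systolic and end diastolic velocity, pulse rate); solves
    transient incompressible Newtonian blood flow with mixed Taylor-Hood
    finite elements; extracts wall shear metrics (time-averaged wall shear
    stress, oscillatory shear index, low-shear and high-oscillation wall
    fractions, boundary pressure ratios); performs plane-strain Mooney-Rivlin
    hyperelastic analysis of the plaque cross-section to obtain plaque
    structural stress; and trains and evaluates an imbalance-corrected
    gradient-boosted-tree event classifier (SMOTE oversampling or random
    undersampling) with Shapley-value feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
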