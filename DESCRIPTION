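Package: drsmethb
Title: Monte Carlo Diffuse Reflectance Simulation and Neural-Network
    Estimation of Methemoglobin and Oxygen Saturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates fiber-probe diffuse reflectance spectra of a four-layer
    human skin model (stratum corneum, epidermis, dermis, subcutaneous fat)
    with wavelength-resolved chromophore absorption (oxy-, deoxy- and
    methemoglobin, water, melanin, bilirubin, beta-carotene, fat) and
    Rayleigh/Mie scattering, using a layered Monte Carlo photon-transport
    engine with a hexagonal six-fiber collection probe. Extracts twelve
    spectral descriptors (peak analysis, signal power, Teager-Kaiser energy
    statistics) with correlation-based feature selection, and fits a
    single-hidden-layer neural network that regresses methemoglobin fraction
    and arterial oxygen saturation from a spectrum, evaluated with MAE, MAPE,
    MSE, RMSE and R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
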