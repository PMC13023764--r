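Package: xpdtdose
Title: Kilovoltage X-Ray Spectrum Optimization for Nanoparticle Dose
    Enhancement in X-Ray-Induced Photodynamic Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale Monte Carlo study of kilovoltage X-ray energy
    selection for nanoparticle-mediated dose enhancement. Generates filtered
    tungsten-anode tube spectra, transports photons through voxelized tumour
    phantoms with and without a NaLuF4:Gd,Tb nanoprobe suspension under the
    kerma approximation, and derives depth-dose, percentage depth dose,
    dose-enhancement-ratio and average-absorbed-dose endpoints. Includes a
    closed-form slab-absorption oracle, bundled elemental photon
    cross-section tables, and a synthetic tumour-growth-inhibition cohort
    generator for correlating simulated dose with treatment outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
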