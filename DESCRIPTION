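Package: pfxverify
Title: Independent Dose and Shot-Time Verification for Gamma Knife Perfexion Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An independent second-check dose engine for Leksell Gamma Knife
    Perfexion radiosurgery plans. Builds a virtual 192-source machine model,
    reconstructs the patient skull surface from skull-scaler measurements by
    spherical-harmonic least squares, ray-traces per-beam tissue depths, and
    evaluates a point dose-rate model combining exponential attenuation,
    inverse-square falloff from virtual sources, and divergence-scaled
    off-axis ratios. Computes per-shot focus doses and times, full 3D dose
    grids, isodose masks and maximum-dose locations, and compares results
    against planning-system reference values with clinical tolerance (3%)
    and action (5%) limits, emitting an HTML verification report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
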