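Package: cacsim
Title: Coronary Artery Calcium Scoring at Reduced Tube Voltage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agatston coronary artery calcium (CAC) scoring with
    tube-voltage-adapted Hounsfield thresholds (120/80/70 kVp), a digital
    chest-phantom and CT-scan simulator with a noise model tied to tube
    voltage, tube current and body-mass index, and the agreement statistics
    used to compare risk stratification between scanning protocols: Cohen's
    kappa, Kendall's tau-b, reclassification rates, Bland-Altman limits of
    agreement and two-way absolute-agreement intraclass correlation. Includes
    an end-to-end in-silico study pipeline and the published 5x5 risk-class
    contingency tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
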