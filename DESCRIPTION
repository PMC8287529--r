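Package: atsasim
Title: Musculoskeletal Simulation of Anatomic Total Shoulder Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale quasi-static musculoskeletal simulator of the
    glenohumeral joint after anatomic total shoulder arthroplasty (ATSA).
    Implements elastic-foundation penalty contact between triangulated
    implant surfaces, polynomial static-optimization muscle recruitment,
    and force-dependent kinematics (FDK) resolution of the three released
    glenohumeral translations, and sweeps arm abduction from 0 to 90
    degrees under an intact rotator cuff and five cuff-deficiency
    scenarios, reporting muscle forces and joint contact forces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    quadprog,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
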