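Package: sporelay
Title: Deterministic Kinetics of Sporulation Initiation in Bacillus subtilis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic kinetic model of the molecular network regulating
    sporulation initiation in Bacillus subtilis: IPTG/LacI-inducible KinA
    expression, signal-driven KinA dimer autophosphorylation, the
    Spo0F-Spo0B-Spo0A phosphorelay with Spo0A~P feedbacks, and the early
    spoII effector arms.  Provides transient integration and steady-state
    solving of the 27-form, 55-reaction network, dose-response scans, local
    relative sensitivity coefficients and global parameter scans, a
    feedback-knockout/compensation analysis, a mean-relative-distance
    goodness-of-agreement metric, the wild-type linear-accumulation
    comparison, SBML Level 3 import/export, and synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
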