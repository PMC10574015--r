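Package: actimetry
Title: Activation-State Metrics and Steered Restraint Schedules for
    Receptor Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying activation of seven-transmembrane
    (7TM) receptors from coordinate data: rigid-body superposition on a
    low-mobility "basement" core, pooled TM6/TM7 RMSD and maximum-distance
    activation indicators scored against active and inactive reference
    conformations, per-residue RMSF profiles with stiff-core detection,
    collective-variable calculators, and a simplified steered-dynamics
    restraint schedule with switching-work accounting.  Includes an
    overdamped Langevin toy engine with analytic free-energy oracles and
    generators for synthetic helical-bundle fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
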