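Package: kirpharm
Title: Dynamic Pharmacophore Screening and Free-Energy Analysis for Kir6
    Channel Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolchain for identifying inward-rectifier potassium
    (Kir6/KATP) channel inhibitors from molecular-dynamics ensembles.
    Provides trajectory-based protein-ligand interaction fingerprints and
    per-residue contact-frequency maps, per-frame structure-based
    pharmacophore model construction with representative-model merging and
    common-hits-approach virtual screening, weighted-histogram (WHAM)
    estimation of umbrella-sampling free-energy profiles with bootstrap
    errors, and Hill-equation dose-response analysis of patch-clamp
    fractional-block data. Includes seeded synthetic-data generators with
    known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
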