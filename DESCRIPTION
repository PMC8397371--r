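Package: corralspt
Title: Single-Molecule Binding Kinetics on Micropatterned Ligand Corrals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-particle tracking experiments on
    micropatterned substrates that display a receptor ligand in mobile
    (supported lipid membrane) and immobile (polymer-grafted) micron-scale
    corrals. Provides a ground-truthed synthetic-data generator (binding
    events, TIRF movie rendering, ligand-channel images, corral intensity
    tables), matched-filter spot detection with subpixel Gaussian refinement,
    nearest-neighbor trajectory linking, region masking and corral mobility
    classification, dwell-time survival analysis with two-order exponential
    decay fitting, appearance-based on-rate estimation, photobleach controls,
    and corral-wise intensity ratio quantification with paired per-cell
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
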