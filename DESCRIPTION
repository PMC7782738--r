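Package: poregate
Title: Pore Hydration, Activation-Gate Geometry and Voltage-Sensor
    Trapping Analysis for Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural and trajectory analysis of voltage-gated ion
    channels, centred on hydrophobic gating of the intracellular
    activation gate. Reads structures (PDB/mmCIF) and trajectories
    (multi-model PDB, DCD) into S4 containers, canonicalizes frames into
    a pore-axis reference frame, and computes cylindrical hydration
    profiles, gate water-count distributions, wetting classification,
    ion permeation events, opposing S6-tail gate distances and their
    free-energy surface, van der Waals pore-diameter profiles, and
    static-structure comparisons (selection RMSD, per-residue
    displacement, gating-charge ion-pair census, alpha versus 3-10 helix
    assignment, Shrake-Rupley buried interface area). Includes Hill
    dose-response and single-exponential kinetics fitting, and seeded
    synthetic-data generators (toy four-fold channel, two-state
    wetting/dewetting trajectories, dose-response and kinetics data) so
    every estimator can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
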