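Package: shockjet
Title: Shock-Damage Analysis for X-Ray Pump-Probe Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing X-ray pump/X-ray probe serial femtosecond
    crystallography (SFX) experiments on liquid microjets, where a first
    (pump) pulse launches a shockwave along the jet and a delayed, spatially
    offset second (probe) pulse records diffraction from sample upstream.
    Provides per-shot filtering on photodiode traces and jet-snapshot
    morphology, per-image diffraction resolution statistics and probe-energy
    binning, half-dataset merging quality metrics (Rsplit, CC1/2, CC*,
    completeness, Wilson B, automatic resolution cutoffs), structural
    comparison of atomic models (Kabsch superposition, displacement fields,
    C-alpha distance-difference matrices, radius of gyration) with bootstrap
    coordinate-uncertainty estimation, pump-probe shock kinematics
    (effective delays, equivalent repetition rates, shock travel distances),
    and a synthetic-data generator with known ground truth that emulates the
    experimental conditions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    bio3d,
    MASS,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
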