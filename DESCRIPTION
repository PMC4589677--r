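Package: lovdyn
Title: Dark- and Light-State Trajectory Analysis for Dimeric LOV Photoreceptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise conformational dynamics of dimeric
    light-oxygen-voltage (LOV) photoreceptor proteins from molecular
    dynamics trajectories. Reads multi-model PDB trajectories, performs
    Kabsch least-squares superposition with RMSD/RMSF profiling (global,
    chain-selective and region-resolved), computes geometric hydrogen-bond
    and salt-bridge occupancy statistics, inter-chain helix crossing-angle
    distributions, and dynamic cross-correlation matrices (DCCM) with
    state averaging and light-minus-dark difference maps. Includes a
    synthetic dimer-trajectory generator with planted correlated motions,
    hydrogen-bond schedules and helix-orientation distributions so every
    analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
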