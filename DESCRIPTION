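Package: allodyn
Title: Structure-Dynamics-Activity Analysis of Allosteric Modulation in
    Protein Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for studying allosteric modulation
    of homodimeric proteins such as the Hsp90 chaperone. Computes residue-pair
    distance-fluctuation (coordination propensity) matrices with replica
    averaging and difference maps, inter-protomer geometry (center-of-mass
    distance distributions, residue contact counts, protomer inertia-axis
    angles and asymmetry series), GROMOS/Daura leader clustering of trajectory
    frames with representative selection for ensemble docking, and a
    structure-dynamics-activity relationship (SDAR) model correlating
    ensemble-averaged ligand efficiency with measured ATPase activity.
    Includes a synthetic-trajectory and synthetic-docking-score generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
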