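Package: junctension
Title: Junctional Intensity Heat Maps, Ablation Recoil, and Actin Binding
    Competition Analysis
Version: 0.1.0
Authors@R:
    person("Packages", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for apical-junction biology in epithelial
    tissues. Builds junction masks from an E-cadherin reference channel,
    computes center-anchored block-averaged fluorescence heat maps with
    posterior/anterior compartment ratio statistics, scores colocalization by
    masked Pearson correlation, estimates junctional tension proxies from
    post-ablation vertex recoil traces, and quantifies actin co-sedimentation
    assays with mass-action equilibrium and competitive-binding models.
    Includes ground-truthed synthetic data generators (Voronoi epithelium
    images, saturating-exponential recoil traces, densitometry lane profiles)
    for validation, plus group-comparison statistics (Student's t, one-way
    ANOVA with Dunnett and Tukey adjustment) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
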