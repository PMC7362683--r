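Package: aldlca
Title: Multigroup Latent Class Trajectories from Accelerated Longitudinal Panel Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying long-term age trajectories of binary household-composition
    markers from short multi-wave aging panels. A multi-wave panel is rearranged into a
    cohort-sequential (accelerated longitudinal) layout in which each birth cohort
    contributes a short, overlapping segment of the age axis; a multigroup latent class
    model with full measurement invariance across cohorts is then estimated by maximum
    likelihood via EM under the design's planned missingness. Includes class-enumeration
    statistics (BIC, relative entropy, class sizes, posterior ranges), per-class age
    trajectory profiles, and a synthetic panel generator with known latent structure,
    attrition, and a refreshment sample for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
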