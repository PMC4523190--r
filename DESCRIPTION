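Package: apexmetry
Title: Computer-Aided Morphometry of the Root-Canal Apex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective image-analysis measurements of apical root-canal
    morphology from calibrated cross-sectional annotations. Builds a medial
    path between two digitally marked canal walls, profiles the canal width
    along it, detects the apical constriction (the narrowest cross-section)
    and the apical foramen (the terminal opening), measures their diameters
    and separation, and computes signed trigonometric distances from an
    endodontic file tip to each landmark together with a position
    classification (short of the constriction, between constriction and
    foramen, or beyond the foramen). Includes reliability statistics
    (intraclass correlation), group-comparison tests (ANOVA, t-test,
    Fisher's exact test), and a synthetic ground-truth apex generator for
    end-to-end validation of the measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
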