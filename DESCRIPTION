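Package: symphysim
Title: Finite-Element Load Analysis of the Pelvis and Pubic Symphysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale musculoskeletal finite-element pipeline for studying
    load transfer through the pelvic ring and the pubic symphysis during
    single-leg stance. Provides CT-density-driven bone constitutive laws
    (power-law elastic moduli, density-dependent yield and strain-softening),
    a Mooney-Rivlin model for the fibrocartilaginous interpubic disc,
    Hill-type muscle force evaluation with static-optimization distribution
    of joint moments, a linear-tetrahedron finite-element solver with tie
    constraints, distributed couplings, fixed and spring supports and
    incremental secant-modulus plasticity, a parametric synthetic two-bone
    plus disc "toy pelvis" generator with named anatomical sets, and
    post-processing to von Mises stress, logarithmic principal strains,
    displacement and support-reaction summaries with load-case comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
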