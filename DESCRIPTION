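Package: sclerashell
Title: Thin-Shell Strain and Stress-Resultant Analysis of Scleral Inflation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates meridional and circumferential Green-Lagrange strains and
    membrane stress resultants of the sclera from tracked edge displacements
    recorded during whole-globe inflation tests, treating the posterior sclera as
    an axisymmetric thin shell of revolution. Includes ellipse fitting of scleral
    edge traces with orthogonal-distance refinement, fourth-order polynomial
    displacement fields, closed-form shell equilibrium, region-averaged
    stress-resultant--strain curves with quality control, quantification metrics
    for experimental glaucoma studies (sampled optic-nerve axon counts, percent
    axon loss, positive integral intraocular-pressure exposure, ocular
    morphometry changes), and a seeded synthetic-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
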