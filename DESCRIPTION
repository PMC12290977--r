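Package: osmotda
Title: Topological Image Analysis and Mass-Transfer Kinetics of Osmotic
    Impregnation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify osmotic impregnation of plant tissue from
    cross-section images and gravimetric kinetics. Computes Euler
    characteristic curves (ECC) of grayscale images by intensity
    filtration on a cubical complex and summarizes impregnation
    uniformity with the Max-Min ECC metric; fits Peleg sorption kinetics
    to water-loss, solute-gain and bioactive-compound uptake series;
    estimates shrinkage-corrected effective diffusivities for cubic
    samples by a modified slope method on the Fickian series solution,
    alongside the classical non-shrinkage slope method and their ratio;
    and correlates the topological metric with stepwise diffusivity. A
    seeded synthetic-data generator (finite-difference diffusion images,
    Peleg-shaped kinetics, exponential shrinkage) makes the full
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
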